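#' Build the k-mer vocabulary
#'
#' Collects the distinct k-mers occurring across all records, ordered by
#' first appearance. The vocabulary indexes the m k-mer nodes of the
#' heterogeneous graph.
#'
#' @param records List of [seq_record()] with \code{kmer_occurrences}
#'   populated (see [split_kmers()]).
#' @param lenk K-mer length; checked against the occurrences.
#' @return Object of class \code{kmer_vocab}: list with \code{kmers}
#'   (character vector, length m), \code{index} (named integer vector mapping
#'   k-mer to 1-based id) and \code{lenk}.
#' @export
build_vocab <- function(records, lenk = 5L) {
  if (length(records) == 0L) stop("empty record set")
  all_kmers <- unlist(lapply(records, function(r) {
    if (is.null(r$kmer_occurrences)) {
      stop("record '", r$id, "' has no kmer_occurrences; run split_kmers()")
    }
    r$kmer_occurrences$kmer
  }), use.names = FALSE)
  kmers <- unique(all_kmers)
  if (any(nchar(kmers) != lenk)) {
    stop("k-mer occurrences do not match lenk = ", lenk)
  }
  index <- stats::setNames(seq_along(kmers), kmers)
  structure(list(kmers = kmers, index = index, lenk = as.integer(lenk)),
            class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab> m=%d lenk=%d\n", length(x$kmers), x$lenk))
  invisible(x)
}

#' Similarity subgraph weight matrix
#'
#' k-mer/k-mer edges connect near-identical k-mers: the weight between
#' distinct k-mers x and y is \code{(lenk - hamming(x, y)) / lenk} when their
#' Hamming distance is at most \code{sim_max_mismatch}, else 0. With the
#' default cutoff of 1 mismatch, similarity edges link single-mutation motif
#' variants, which is what the first attention layer pools over. The matrix
#' is symmetric with zero diagonal.
#'
#' @param vocab A [build_vocab()] result.
#' @param sim_max_mismatch Maximum Hamming distance carrying an edge
#'   (default 1).
#' @return Sparse symmetric m x m \code{Matrix::dgCMatrix}.
#' @export
build_similarity_matrix <- function(vocab, sim_max_mismatch = 1L) {
  m <- length(vocab$kmers)
  lenk <- vocab$lenk
  chars <- do.call(rbind, strsplit(vocab$kmers, ""))  # m x lenk
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  if (sim_max_mismatch >= 1L && m > 1L) {
    # enumerate mutation neighborhoods rather than all m^2 pairs
    for (d in seq_len(min(sim_max_mismatch, lenk))) {
      if (d == 1L) {
        for (pos in seq_len(lenk)) {
          key <- apply(chars[, -pos, drop = FALSE], 1L, paste, collapse = "")
          groups <- split(seq_len(m), key)
          for (g in groups) {
            if (length(g) < 2L) next
            pr <- utils::combn(g, 2L)
            ii <- c(ii, pr[1L, ]); jj <- c(jj, pr[2L, ])
            ww <- c(ww, rep((lenk - 1) / lenk, ncol(pr)))
          }
        }
      } else {
        # small-m fallback for larger cutoffs: direct pair scan
        for (x in seq_len(m - 1L)) for (y in (x + 1L):m) {
          hd <- sum(chars[x, ] != chars[y, ])
          if (hd == d) {
            ii <- c(ii, x); jj <- c(jj, y)
            ww <- c(ww, (lenk - hd) / lenk)
          }
        }
      }
    }
  }
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(m, m),
                            dimnames = list(vocab$kmers, vocab$kmers))
  methods::as(W, "CsparseMatrix")
}

#' Coexisting subgraph weight matrix
#'
#' k-mer/k-mer edges weighted by co-occurrence: the weight between distinct
#' k-mers x and y is the fraction of positive sequences containing both.
#' Negatives are per-sequence shuffles and would only inject compositional
#' noise, so by default only positives contribute; set
#' \code{positives_only = FALSE} to use every record. Symmetric, zero
#' diagonal.
#'
#' @param vocab A [build_vocab()] result.
#' @param records List of [seq_record()] (k-mer split).
#' @param positives_only Use only label-1 records (default TRUE).
#' @return Sparse symmetric m x m \code{Matrix::dgCMatrix}.
#' @export
build_coexisting_matrix <- function(vocab, records, positives_only = TRUE) {
  if (positives_only) records <- records[record_labels(records) == 1L]
  if (length(records) == 0L) stop("no positive records for coexisting matrix")
  m <- length(vocab$kmers)
  n <- length(records)
  # binary incidence: k-mer x present in sequence z
  ii <- integer(0); jj <- integer(0)
  for (z in seq_len(n)) {
    ids <- unique(vocab$index[records[[z]]$kmer_occurrences$kmer])
    ids <- ids[!is.na(ids)]
    ii <- c(ii, ids); jj <- c(jj, rep(z, length(ids)))
  }
  B <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(m, n))
  C <- Matrix::tcrossprod(B)            # co-occurrence counts, m x m
  Matrix::diag(C) <- 0
  W <- C / n
  dimnames(W) <- list(vocab$kmers, vocab$kmers)
  methods::as(Matrix::drop0(W), "CsparseMatrix")
}

#' Inclusive subgraph weight matrix
#'
#' k-mer/sequence edges: entry (x, z) is the number of occurrences of k-mer x
#' in sequence z (raw count; the learned projection of the second layer
#' handles any rescaling).
#'
#' @param vocab A [build_vocab()] result.
#' @param records List of [seq_record()] (k-mer split).
#' @return Sparse m x n \code{Matrix::dgCMatrix}, columns named by record id.
#' @export
build_inclusive_matrix <- function(vocab, records) {
  m <- length(vocab$kmers)
  n <- length(records)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (z in seq_len(n)) {
    occ <- records[[z]]$kmer_occurrences
    if (is.null(occ)) stop("record '", records[[z]]$id, "' not k-mer split")
    ids <- vocab$index[occ$kmer]
    keep <- !is.na(ids)
    tab <- table(ids[keep])
    ii <- c(ii, as.integer(names(tab)))
    jj <- c(jj, rep(z, length(tab)))
    xx <- c(xx, as.numeric(tab))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n),
                       dimnames = list(vocab$kmers, record_ids(records)))
}

#' Assemble the heterogeneous graph
#'
#' Convenience constructor building the vocabulary and the three subgraph
#' weight matrices from a set of k-mer-split records.
#'
#' @param records List of [seq_record()] with occurrences populated. The
#'   inclusive and coexisting matrices are built from these records.
#' @param lenk K-mer length (default 5).
#' @param vocab Optional pre-built [build_vocab()] (e.g. over the full
#'   dataset when \code{records} is only the training part, so that held-out
#'   k-mers have nodes).
#' @param sim_max_mismatch Passed to [build_similarity_matrix()].
#' @param positives_only Passed to [build_coexisting_matrix()].
#' @return Object of class \code{het_graph}: list with \code{vocab},
#'   \code{records}, \code{W_sim}, \code{W_co}, \code{W_inclu}, \code{labels}
#'   and the builder parameters.
#' @export
build_het_graph <- function(records, lenk = 5L, vocab = NULL,
                            sim_max_mismatch = 1L, positives_only = TRUE) {
  if (is.null(vocab)) vocab <- build_vocab(records, lenk)
  structure(
    list(
      vocab = vocab,
      records = records,
      W_sim = build_similarity_matrix(vocab, sim_max_mismatch),
      W_co = build_coexisting_matrix(vocab, records, positives_only),
      W_inclu = build_inclusive_matrix(vocab, records),
      labels = record_labels(records),
      params = list(lenk = vocab$lenk, sim_max_mismatch = sim_max_mismatch,
                    positives_only = positives_only)
    ),
    class = "het_graph"
  )
}

#' @export
print.het_graph <- function(x, ...) {
  cat(sprintf(
    "<het_graph> m=%d k-mers, n=%d sequences | sim edges=%d co edges=%d inclu edges=%d\n",
    length(x$vocab$kmers), length(x$records),
    Matrix::nnzero(x$W_sim) / 2, Matrix::nnzero(x$W_co) / 2,
    Matrix::nnzero(x$W_inclu)))
  invisible(x)
}

#' Adjacency statistics for k-mer coexisting probabilities
#'
#' Counts, over positive sequences, (a) for each k-mer x the number of
#' positive sequences containing x, and (b) for each ordered pair (x, y) the
#' number of positive sequences in which some occurrence of y starts exactly
#' one base after an occurrence of x. These drive the seed-chaining step of
#' motif reconstruction.
#'
#' @param vocab A [build_vocab()] result.
#' @param records List of [seq_record()]; only label-1 records are used.
#' @return Object of class \code{coexist_stats}: list with
#'   \code{pair_counts} (named integer vector, names \code{"x>y"}),
#'   \code{kmer_counts} (named integer vector) and \code{n_pos}.
#' @export
coexist_stats <- function(vocab, records) {
  pos <- records[record_labels(records) == 1L]
  if (length(pos) == 0L) stop("no positive records")
  pair_keys <- character(0)
  kmer_keys <- character(0)
  for (r in pos) {
    km <- r$kmer_occurrences$kmer
    kmer_keys <- c(kmer_keys, unique(km))
    nk <- length(km)
    if (nk >= 2L) {
      pair_keys <- c(pair_keys,
                     unique(paste0(km[-nk], ">", km[-1L])))
    }
  }
  pc <- table(pair_keys)
  kc <- table(kmer_keys)
  structure(
    list(pair_counts = stats::setNames(as.integer(pc), names(pc)),
         kmer_counts = stats::setNames(as.integer(kc), names(kc)),
         n_pos = length(pos)),
    class = "coexist_stats"
  )
}

#' Coexisting probability of two k-mers
#'
#' Conditional probability that k-mer y starts exactly one base after k-mer x
#' within a positive sequence containing x:
#' \code{P(y at offset+1 | x) = pair_count(x, y) / kmer_count(x)}. This is
#' the statistic that decides whether two overlapping k-mer seeds are chained
#' into a longer candidate binding site.
#'
#' @param stats A [coexist_stats()] result.
#' @param x,y K-mer strings.
#' @return Probability in \[0, 1\].
#' @export
coexist_probability <- function(stats, x, y) {
  kc <- stats$kmer_counts[x]
  if (is.na(kc) || kc == 0L) {
    stop("k-mer '", x, "' does not occur in any positive sequence")
  }
  pc <- stats$pair_counts[paste0(x, ">", y)]
  if (is.na(pc)) pc <- 0L
  as.numeric(pc) / as.numeric(kc)
}

#' Serialize a heterogeneous graph to plain text
#'
#' Writes each weight matrix as a sparse triplet TSV (row, col, weight; ids
#' are k-mer strings and sequence ids) plus a JSON manifest with m, n, lenk
#' and builder parameters.
#'
#' @param graph A [build_het_graph()] result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_het_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump_triplets <- function(W, path) {
    T <- Matrix::mat2triplet(W)
    utils::write.table(
      data.frame(row = rownames(W)[T$i], col = colnames(W)[T$j],
                 weight = T$x),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  dump_triplets(graph$W_sim, file.path(dir, "w_sim.tsv"))
  dump_triplets(graph$W_co, file.path(dir, "w_co.tsv"))
  dump_triplets(graph$W_inclu, file.path(dir, "w_inclu.tsv"))
  jsonlite::write_json(
    list(m = length(graph$vocab$kmers), n = length(graph$records),
         lenk = graph$vocab$lenk, params = graph$params),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
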
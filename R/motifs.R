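# Motif extraction from trained inclusive attention coefficients: positive
# rows are denoised against the mean negative coefficient (background), any
# (sequence, k-mer) cell left strictly positive on either branch seeds an
# occurrence, seeds are chained by k-mer coexisting probability into
# candidate binding sites, overlapping candidates are unioned, and the
# instances of each width are summarised as a PPM.

#' Collect label-split inclusive attention matrices
#'
#' Runs the trained model (without dropout) over \code{records} and gathers
#' the inclusive attention coefficient rows, split by label into positive
#' matrices \code{B1_sim}/\code{B1_co} and negative matrices
#' \code{B0_sim}/\code{B0_co}. The mean coefficient of the negative matrices
#' -- taken over inclusive-edge cells only, since non-edges carry no
#' coefficient -- is the background noise, and the denoised positive
#' matrices are \code{dnB1 = B1 - background}. Non-edge cells are \code{NA}
#' throughout (absent, not zero).
#'
#' @param model A trained [train_gat()] model.
#' @param records Labeled, k-mer-split [seq_record()] list containing both
#'   classes.
#' @return Object of class \code{attention_split}: list with \code{B1_sim},
#'   \code{B1_co}, \code{B0_sim}, \code{B0_co} (rows named by record id,
#'   columns by k-mer), \code{background_sim}, \code{background_co},
#'   \code{dnB1_sim}, \code{dnB1_co}.
#' @export
collect_attention <- function(model, records) {
  labels <- record_labels(records)
  if (!any(labels == 0L)) stop("no negative records: background undefined")
  if (!any(labels == 1L)) stop("no positive records: nothing to denoise")
  X <- inclusive_counts(model$vocab, records)
  fw <- gat_forward(model$params, model$pre, X, dropout = 0,
                    slope = model$config$leaky_slope)
  name_mat <- function(B) {
    B[!fw$AI] <- NA_real_
    dimnames(B) <- list(record_ids(records), model$vocab$kmers)
    B
  }
  Bs <- name_mat(fw$l2_sim$beta)
  Bc <- name_mat(fw$l2_co$beta)
  pos <- labels == 1L
  background_sim <- mean(Bs[!pos, , drop = FALSE], na.rm = TRUE)
  background_co <- mean(Bc[!pos, , drop = FALSE], na.rm = TRUE)
  structure(
    list(B1_sim = Bs[pos, , drop = FALSE], B1_co = Bc[pos, , drop = FALSE],
         B0_sim = Bs[!pos, , drop = FALSE], B0_co = Bc[!pos, , drop = FALSE],
         background_sim = background_sim, background_co = background_co,
         dnB1_sim = Bs[pos, , drop = FALSE] - background_sim,
         dnB1_co = Bc[pos, , drop = FALSE] - background_co),
    class = "attention_split"
  )
}

#' Find k-mer seeds from denoised attention
#'
#' A k-mer occurrence on a positive sequence is a seed when its denoised
#' similarity or coexisting coefficient is strictly positive
#' (\code{dnB1_sim(z, x) > 0} OR \code{dnB1_co(z, x) > 0}). The coefficient
#' is defined per (sequence, k-mer) pair; because the same k-mer can occur
#' at several offsets, a qualifying pair emits one seed per occurrence so
#' the positional merging step can run.
#'
#' @param att An [collect_attention()] result.
#' @param records The records passed to [collect_attention()] (positives are
#'   looked up by id for their occurrence lists).
#' @return data.frame with columns \code{sequence_id}, \code{kmer},
#'   \code{offset} (0-based), \code{dn_sim}, \code{dn_co}, ordered by
#'   sequence then offset. Zero rows if nothing qualifies.
#' @export
find_kmer_seeds <- function(att, records) {
  by_id <- stats::setNames(records, record_ids(records))
  out <- list()
  for (z in rownames(att$dnB1_sim)) {
    occ <- by_id[[z]]$kmer_occurrences
    ds <- att$dnB1_sim[z, occ$kmer]
    dc <- att$dnB1_co[z, occ$kmer]
    hit <- which((!is.na(ds) & ds > 0) | (!is.na(dc) & dc > 0))
    if (length(hit) == 0L) next
    out[[z]] <- data.frame(
      sequence_id = z, kmer = occ$kmer[hit], offset = occ$offset[hit],
      dn_sim = unname(ds[hit]), dn_co = unname(dc[hit]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(sequence_id = character(0), kmer = character(0),
                      offset = integer(0), dn_sim = numeric(0),
                      dn_co = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chain k-mer seeds into candidate binding sites
#'
#' Within each sequence, seeds sorted by offset are chained left to right:
#' two seeds at consecutive offsets (difference exactly 1) are joined when
#' the coexisting probability of the left k-mer being followed by the right
#' one is at least \code{theta_co}. Each maximal chain becomes one candidate
#' spanning from its first offset to its last offset plus \code{lenk}
#' (0-based half-open); an unchained seed yields a lenk-wide candidate.
#' Larger offset gaps always break chains, because the coexisting statistic
#' is defined for immediate adjacency only.
#'
#' @param seeds A [find_kmer_seeds()] data.frame.
#' @param stats A [coexist_stats()] result built from positive training
#'   sequences.
#' @param records Records supplying the subsequences.
#' @param theta_co Chaining threshold in \[0, 1\] (default 0.5).
#' @param lenk K-mer length.
#' @return data.frame of candidate instances: \code{sequence_id},
#'   \code{start}, \code{end} (0-based half-open), \code{width},
#'   \code{subsequence}, \code{n_seeds}.
#' @export
merge_seeds <- function(seeds, stats, records, theta_co = 0.5, lenk = 5L) {
  by_id <- stats::setNames(records, record_ids(records))
  out <- list()
  for (z in unique(seeds$sequence_id)) {
    s <- seeds[seeds$sequence_id == z, ]
    s <- s[order(s$offset), ]
    chain_start <- s$offset[1L]
    prev_off <- s$offset[1L]
    prev_kmer <- s$kmer[1L]
    n_in_chain <- 1L
    flush <- function(start, end_off, n) {
      data.frame(sequence_id = z, start = start, end = end_off + lenk,
                 width = end_off + lenk - start,
                 subsequence = substr(by_id[[z]]$sequence, start + 1L,
                                      end_off + lenk),
                 n_seeds = n, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(s))[-1L]) {
      # a left k-mer absent from the positive training set has no adjacency
      # statistic; such a junction never chains
      p_adj <- if (is.na(stats$kmer_counts[prev_kmer])) 0 else
        coexist_probability(stats, prev_kmer, s$kmer[i])
      joined <- s$offset[i] == prev_off + 1L && p_adj >= theta_co
      if (joined) {
        n_in_chain <- n_in_chain + 1L
      } else {
        out[[length(out) + 1L]] <- flush(chain_start, prev_off, n_in_chain)
        chain_start <- s$offset[i]
        n_in_chain <- 1L
      }
      prev_off <- s$offset[i]
      prev_kmer <- s$kmer[i]
    }
    out[[length(out) + 1L]] <- flush(chain_start, prev_off, n_in_chain)
  }
  if (length(out) == 0L) {
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), width = integer(0),
                      subsequence = character(0), n_seeds = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Union overlapping candidate binding sites
#'
#' Within each sequence, candidates sharing at least one base are merged
#' into a single instance spanning the union of their intervals, so the
#' final instances per sequence are pairwise disjoint. This is what turns
#' chains of different seeds into binding sites of multiple lengths.
#'
#' @param candidates A [merge_seeds()] data.frame.
#' @param records Records supplying the subsequences.
#' @return data.frame with \code{sequence_id}, \code{start}, \code{end},
#'   \code{width}, \code{subsequence}.
#' @export
merge_overlaps <- function(candidates, records) {
  if (nrow(candidates) == 0L) {
    return(candidates[, c("sequence_id", "start", "end", "width",
                          "subsequence")])
  }
  by_id <- stats::setNames(records, record_ids(records))
  out <- list()
  for (z in unique(candidates$sequence_id)) {
    cc <- candidates[candidates$sequence_id == z, ]
    # 0-based half-open -> 1-based closed IRanges
    merged <- IRanges::reduce(IRanges::IRanges(start = cc$start + 1L,
                                               end = cc$end))
    st <- IRanges::start(merged) - 1L
    en <- IRanges::end(merged)
    out[[z]] <- data.frame(
      sequence_id = z, start = st, end = en, width = en - st,
      subsequence = substr(rep(by_id[[z]]$sequence, length(st)),
                           st + 1L, en),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build position probability matrices from binding-site instances
#'
#' Instances are grouped by exact width; each group with at least
#' \code{min_support} members yields a motif model whose PPM is the
#' column-wise base frequency of the aligned instances with an additive
#' pseudocount. Groups below support are dropped with a message.
#'
#' @param instances A [merge_overlaps()] (or [merge_seeds()]) data.frame.
#' @param min_support Minimum instances per width (default 5).
#' @param pseudocount Additive pseudocount per base and column
#'   (default 0.01).
#' @return List of \code{motif_model} objects (fields \code{width},
#'   \code{ppm}, \code{support}, \code{instances}), sorted by decreasing
#'   support.
#' @export
build_motifs <- function(instances, min_support = 5L, pseudocount = 0.01) {
  groups <- split(instances, instances$width)
  dropped <- 0L
  motifs <- list()
  for (g in groups) {
    if (nrow(g) < min_support) { dropped <- dropped + 1L; next }
    w <- g$width[1L]
    mat <- do.call(rbind, strsplit(g$subsequence, ""))
    counts <- vapply(seq_len(w), function(j) {
      tabulate(factor(mat[, j], levels = DNA_BASES), nbins = 4L)
    }, numeric(4))
    counts <- counts + pseudocount
    ppm <- sweep(counts, 2L, colSums(counts), "/")
    rownames(ppm) <- DNA_BASES
    motifs[[length(motifs) + 1L]] <- structure(
      list(width = w, ppm = ppm, support = nrow(g), instances = g),
      class = "motif_model")
  }
  if (dropped > 0L) {
    message(dropped, " width group(s) below min_support dropped")
  }
  motifs[order(-vapply(motifs, function(m) m$support, numeric(1)))]
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> width=%d support=%d consensus=%s\n",
              x$width, x$support,
              paste(DNA_BASES[apply(x$ppm, 2L, which.max)], collapse = "")))
  invisible(x)
}

#' Write motifs in MEME minimal format
#'
#' Version-4 minimal motif exchange format, the integration point for
#' downstream matching and enrichment tools. One
#' \code{letter-probability matrix} block per motif; probabilities are
#' printed to 6 decimals and round-trip bit-identically through
#' [read_meme()] at that precision.
#'
#' @param motifs Nonempty list of motif models from [build_motifs()].
#' @param path Output file.
#' @param background_freqs Length-4 A/C/G/T background; defaults to uniform.
#'   In the pipeline the empirical composition of the positive sequences is
#'   passed.
#' @return \code{path}, invisibly.
#' @export
write_meme <- function(motifs, path, background_freqs = rep(0.25, 4)) {
  if (length(motifs) == 0L) stop("no motifs to write")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", background_freqs[1],
                       background_freqs[2], background_freqs[3],
                       background_freqs[4]), ""), con)
  for (i in seq_along(motifs)) {
    mm <- motifs[[i]]
    writeLines(sprintf("MOTIF motif_%d", i), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      mm$width, mm$support), con)
    for (j in seq_len(mm$width)) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", mm$ppm[1, j], mm$ppm[2, j],
                         mm$ppm[3, j], mm$ppm[4, j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal format motif file
#'
#' Parses the letter-probability matrices written by [write_meme()] (or any
#' minimal-format file over the ACGT alphabet).
#'
#' @param path MEME file.
#' @return List of \code{motif_model} objects (instances empty).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF", lines[i])) {
      hdr <- i + 1L
      while (hdr <= length(lines) &&
             !grepl("^letter-probability matrix", lines[hdr])) {
        hdr <- hdr + 1L
      }
      w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
      ns <- if (grepl("nsites=", lines[hdr])) {
        as.integer(sub(".*nsites= *([0-9]+).*", "\\1", lines[hdr]))
      } else NA_integer_
      rows <- lines[(hdr + 1L):(hdr + w)]
      ppm <- t(vapply(rows, function(l) {
        as.numeric(strsplit(trimws(l), "\\s+")[[1]])
      }, numeric(4), USE.NAMES = FALSE))
      ppm <- t(ppm)  # 4 x w, rows A/C/G/T
      rownames(ppm) <- DNA_BASES
      motifs[[length(motifs) + 1L]] <- structure(
        list(width = w, ppm = ppm, support = ns, instances = NULL),
        class = "motif_model")
      i <- hdr + w + 1L
    } else {
      i <- i + 1L
    }
  }
  motifs
}

#' Write binding-site instances as BED
#'
#' 0-based half-open intervals on the source sequences; the name column
#' carries the subsequence.
#'
#' @param instances A [merge_overlaps()] data.frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_tfbs_bed <- function(instances, path) {
  bed <- data.frame(chrom = instances$sequence_id, start = instances$start,
                    end = instances$end, name = instances$subsequence,
                    score = 0L, strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Best alignment correlation between a motif PPM and a reference PPM
#'
#' Slides the narrower matrix along the wider one and reports the best mean
#' per-column Pearson correlation across the overlap -- the recovery score
#' used to judge whether a discovered motif matches a planted (or database)
#' motif.
#'
#' @param ppm,ref 4 x w column-stochastic matrices (widths may differ).
#' @return Best mean per-column correlation in \[-1, 1\].
#' @export
ppm_correlation <- function(ppm, ref) {
  if (ncol(ppm) < ncol(ref)) { tmp <- ppm; ppm <- ref; ref <- tmp }
  wr <- ncol(ref)
  best <- -Inf
  for (off in 0:(ncol(ppm) - wr)) {
    cors <- vapply(seq_len(wr), function(j) {
      a <- ppm[, off + j]; b <- ref[, j]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      stats::cor(a, b)
    }, numeric(1))
    best <- max(best, mean(cors))
  }
  best
}
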
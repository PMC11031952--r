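#' Read labeled sequences from FASTA
#'
#' Labels are encoded in the FASTA headers as a suffix separated by
#' \code{label_sep}, e.g. \code{>peak17|1}. Records whose sequence contains
#' symbols outside A/C/G/T (typically N) are dropped with a message giving the
#' count, since the k-mer graph is defined over the 4-letter alphabet.
#'
#' @param path FASTA file.
#' @param label_sep Separator between id and label in the header (default
#'   \code{"|"}).
#' @return List of [seq_record()] in file order.
#' @export
read_seq_fasta <- function(path, label_sep = "|") {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) return(list())
  headers <- names(set)
  seqs <- toupper(as.character(set))
  sep <- regexpr(paste0("\\", label_sep, "[01]$"), headers)
  bad <- which(sep < 0L)
  if (length(bad) > 0L) {
    stop("FASTA header without a '", label_sep,
         "0' / '", label_sep, "1' label suffix: '", headers[bad[1]], "'")
  }
  ids <- substr(headers, 1L, sep - 1L)
  labels <- as.integer(substr(headers, sep + 1L, nchar(headers)))
  keep <- !grepl("[^ACGT]", seqs)
  if (any(!keep)) {
    message(sum(!keep), " record(s) with non-ACGT symbols dropped")
  }
  mapply(seq_record, ids[keep], seqs[keep], labels[keep],
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write labeled sequences to FASTA
#'
#' Inverse of [read_seq_fasta()]: headers are \code{id|label}.
#'
#' @param records List of [seq_record()].
#' @param path Output file.
#' @param label_sep Separator (default \code{"|"}).
#' @return \code{path}, invisibly.
#' @export
write_seq_fasta <- function(records, path, label_sep = "|") {
  set <- Biostrings::DNAStringSet(record_sequences(records))
  names(set) <- paste0(record_ids(records), label_sep, record_labels(records))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Cut fixed-length windows around BED interval centers
#'
#' Reproduces the footprint-to-sequence step: each interval (a footprint call)
#' is replaced by a window of \code{window_len} bp centered on its midpoint,
#' and the window sequence is extracted from the reference. Intervals are
#' 0-based half-open; the center is \code{floor((start + end) / 2)} and the
#' window spans \code{center - w} .. \code{center + w} inclusive for
#' \code{window_len = 2w + 1}. Windows that would run past a chromosome end,
#' or whose chromosome carries non-ACGT symbols in the window, are skipped
#' with a message. All returned records are labeled positive.
#'
#' @param bed Path to a BED file (>= 3 columns) or a data.frame with columns
#'   \code{chrom}, \code{start}, \code{end}.
#' @param reference_fasta Path to the reference FASTA.
#' @param window_len Window length in bp, odd (default 101).
#' @return List of [seq_record()] with label 1; ids are
#'   \code{chrom:start-end} of the window (0-based half-open).
#' @export
cut_windows <- function(bed, reference_fasta, window_len = 101L) {
  window_len <- as.integer(window_len)
  if (window_len %% 2L != 1L) stop("window_len must be odd")
  if (is.character(bed)) {
    bed <- utils::read.table(bed, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[, 1:3]
    names(bed) <- c("chrom", "start", "end")
  }
  ref <- Biostrings::readDNAStringSet(reference_fasta)
  # FASTA headers may carry descriptions after the first word
  names(ref) <- sub("\\s.*$", "", names(ref))
  half <- (window_len - 1L) %/% 2L
  missing_chrom <- setdiff(unique(bed$chrom), names(ref))
  if (length(missing_chrom) > 0L) {
    stop("chromosome(s) absent from reference: ",
         paste(missing_chrom, collapse = ", "))
  }
  records <- list()
  skipped <- 0L
  for (i in seq_len(nrow(bed))) {
    chrom <- bed$chrom[i]
    center <- (bed$start[i] + bed$end[i]) %/% 2L  # 0-based
    w_start0 <- center - half                      # 0-based inclusive
    w_end0 <- center + half + 1L                   # 0-based exclusive
    clen <- Biostrings::width(ref[chrom])
    if (w_start0 < 0L || w_end0 > clen) {
      skipped <- skipped + 1L
      next
    }
    s <- toupper(as.character(
      Biostrings::subseq(ref[[chrom]], start = w_start0 + 1L, end = w_end0)))
    if (grepl("[^ACGT]", s)) {
      skipped <- skipped + 1L
      next
    }
    id <- sprintf("%s:%d-%d", chrom, w_start0, w_end0)
    records[[length(records) + 1L]] <- seq_record(id, s, 1L)
  }
  if (skipped > 0L) {
    message(skipped, " interval(s) skipped (out of bounds or ambiguous bases)")
  }
  records
}

#' Generate a shuffled negative from a positive sequence
#'
#' Negatives are per-sequence nucleotide shuffles of the positives, so each
#' negative preserves its positive's mononucleotide composition exactly while
#' destroying positional motif structure. A dinucleotide-preserving shuffle
#' (Altschul-Erickson Eulerian-path style) is available as an option.
#'
#' Uses the R session RNG; call [set.seed()] beforehand for reproducibility.
#'
#' @param record A positive [seq_record()] (label 1).
#' @param method \code{"mono"} (default) permutes nucleotides;
#'   \code{"dinuc"} preserves dinucleotide counts.
#' @return A new [seq_record()] with label 0 and id \code{<id>_shuf}.
#' @export
shuffle_negative <- function(record, method = c("mono", "dinuc")) {
  method <- match.arg(method)
  if (record$label != 1L) {
    stop("shuffle_negative expects a positive record (label 1)")
  }
  chars <- strsplit(record$sequence, "")[[1]]
  shuffled <- switch(method,
    mono = paste(sample(chars), collapse = ""),
    dinuc = dinucleotide_shuffle(chars)
  )
  seq_record(paste0(record$id, "_shuf"), shuffled, 0L)
}

# Altschul-Erickson doublet-preserving shuffle: random walk over the
# last-letter multigraph, retrying until the Eulerian condition (all edges
# used) is met. Sequences here are ~100 bp so retries are cheap.
dinucleotide_shuffle <- function(chars) {
  n <- length(chars)
  if (n <= 2L) return(paste(chars, collapse = ""))
  repeat {
    edges <- split(chars[-1L], chars[-n])
    edges <- lapply(edges, sample)
    used <- lapply(edges, function(e) 0L)
    out <- character(n)
    out[1L] <- chars[1L]
    ok <- TRUE
    for (i in 2L:n) {
      cur <- out[i - 1L]
      k <- used[[cur]] + 1L
      if (k > length(edges[[cur]])) { ok <- FALSE; break }
      out[i] <- edges[[cur]][k]
      used[[cur]] <- k
    }
    if (ok && all(mapply(function(u, e) u == length(e), used, edges))) {
      return(paste(out, collapse = ""))
    }
  }
}

#' Split a sequence into overlapping k-mers
#'
#' Slides a window of size \code{lenk} with step 1 across the sequence,
#' populating \code{kmer_occurrences} with one row per window: the k-mer
#' string and its 0-based offset. A sequence of length L yields exactly
#' \code{L - lenk + 1} occurrences.
#'
#' @param record A [seq_record()], or a list of them.
#' @param lenk K-mer length (default 5).
#' @return The record(s) with \code{kmer_occurrences} populated.
#' @export
split_kmers <- function(record, lenk = 5L) {
  if (is.list(record) && !inherits(record, "seq_record")) {
    return(lapply(record, split_kmers, lenk = lenk))
  }
  lenk <- as.integer(lenk)
  L <- nchar(record$sequence)
  if (lenk < 1L || lenk > L) {
    stop("lenk must be in 1..", L, ", got ", lenk)
  }
  offsets <- 0:(L - lenk)
  kmers <- substring(record$sequence, offsets + 1L, offsets + lenk)
  record$kmer_occurrences <- data.frame(
    kmer = kmers, offset = offsets, stringsAsFactors = FALSE)
  record
}

#' Stratified train/validation/test split
#'
#' Shuffles records deterministically under \code{seed} and partitions them
#' into train/validation/test by \code{fractions}, stratified by label so each
#' part keeps the overall class balance to within one record. Stratification
#' matters downstream: the attention-background denoising step assumes
#' negatives are well represented.
#'
#' @param records List of [seq_record()].
#' @param fractions Numeric length-3 summing to 1 (default c(0.8, 0.1, 0.1)).
#' @param seed Integer RNG seed.
#' @return Object of class \code{dataset_split}: list with \code{train},
#'   \code{validation}, \code{test} (lists of records), plus
#'   \code{fractions} and \code{seed}.
#' @export
make_split <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3L) {
    stop("fractions must be three numbers summing to 1")
  }
  if (length(records) < 10L) {
    stop("need at least 10 records to honor the smallest split fraction")
  }
  labels <- record_labels(records)
  assign_part <- function(idx) {
    # deterministic shuffle within stratum, then contiguous cut
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_tr <- round(fractions[1] * n)
    n_va <- round(fractions[2] * n)
    n_tr <- min(n_tr, n)
    n_va <- min(n_va, n - n_tr)
    part <- rep(3L, n)
    part[seq_len(n_tr)] <- 1L
    if (n_va > 0L) part[n_tr + seq_len(n_va)] <- 2L
    split(idx, part)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  parts <- lapply(split(seq_along(records), labels), assign_part)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  pick <- function(k) {
    idx <- sort(unlist(lapply(parts, function(p) p[[as.character(k)]]),
                       use.names = FALSE))
    records[idx]
  }
  structure(
    list(train = pick(1L), validation = pick(2L), test = pick(3L),
         fractions = fractions, seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train=%d validation=%d test=%d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}
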
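DNA_BASES <- c("A", "C", "G", "T")

#' Specify a planted motif for synthetic benchmark data
#'
#' Describes the motif planted into synthetic positive sequences: a 4 x w
#' position probability matrix (PPM), the fraction of positives that receive
#' an instance, and the background nucleotide model used outside instances.
#' Instance positions are uniform over valid offsets.
#'
#' @param ppm 4 x w numeric matrix, rows A/C/G/T, columns summing to 1.
#' @param occurrence_rate Fraction of positive sequences receiving an
#'   instance, in (0, 1] (default 1).
#' @param background Length-4 nucleotide probabilities for background
#'   positions (default uniform).
#' @return Object of class \code{planted_motif_spec}.
#' @export
planted_motif_spec <- function(ppm, occurrence_rate = 1,
                               background = rep(0.25, 4)) {
  ppm <- as.matrix(ppm)
  if (nrow(ppm) != 4L) stop("ppm must have 4 rows (A, C, G, T)")
  if (any(abs(colSums(ppm) - 1) > 1e-9) || any(ppm < 0)) {
    stop("ppm columns must be nonnegative and sum to 1")
  }
  if (occurrence_rate <= 0 || occurrence_rate > 1) {
    stop("occurrence_rate must be in (0, 1]")
  }
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 probabilities summing to 1")
  }
  rownames(ppm) <- DNA_BASES
  structure(list(ppm = ppm, occurrence_rate = occurrence_rate,
                 background = as.numeric(background)),
            class = "planted_motif_spec")
}

#' Default planted motif used by the bundled benchmark
#'
#' An 8-column PPM around the AP-1-like consensus TGACTCAG with dominant-base
#' probability 0.92 per column (about 1.5 bits of information per column) --
#' a strongly informative motif of the kind footprint-derived ATAC-seq
#' positives carry.
#'
#' @param consensus Consensus string (default \code{"TGACTCAG"}).
#' @param dominant Probability of the consensus base per column (default
#'   0.92); the remaining mass is spread evenly over the other three bases.
#' @return 4 x nchar(consensus) PPM matrix.
#' @export
default_planted_ppm <- function(consensus = "TGACTCAG", dominant = 0.92) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  w <- length(bases)
  ppm <- matrix((1 - dominant) / 3, nrow = 4L, ncol = w,
                dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(w)) ppm[bases[j], j] <- dominant
  ppm
}

#' Generate a synthetic planted-motif dataset
#'
#' Emulates the footprint-derived study design: \code{n_pos} positive
#' sequences of length \code{seq_len} drawn from the background model, each
#' receiving (with probability \code{spec$occurrence_rate}) one motif
#' instance sampled column-wise from \code{spec$ppm} and planted at a
#' uniform-random valid offset; one negative per positive produced by
#' [shuffle_negative()]. All records are k-mer split with \code{lenk}.
#' Generation is bit-reproducible given \code{seed}.
#'
#' @param spec A [planted_motif_spec()].
#' @param n_pos Number of positive sequences (>= 1).
#' @param seq_len Sequence length (default 101).
#' @param lenk K-mer length for [split_kmers()] (default 5).
#' @param seed Integer RNG seed.
#' @return List with \code{records} (positives then negatives, k-mer split)
#'   and \code{ground_truth}: data.frame (sequence_id, offset, instance) of
#'   every planted occurrence, offsets 0-based.
#' @export
generate_synthetic <- function(spec, n_pos, seq_len = 101L, lenk = 5L,
                               seed = 1L) {
  stopifnot(inherits(spec, "planted_motif_spec"))
  n_pos <- as.integer(n_pos)
  if (n_pos < 1L) stop("n_pos must be >= 1")
  w <- ncol(spec$ppm)
  if (w >= seq_len) stop("motif width must be smaller than seq_len")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  positives <- vector("list", n_pos)
  gt_id <- character(0); gt_off <- integer(0); gt_inst <- character(0)
  for (i in seq_len(n_pos)) {
    chars <- sample(DNA_BASES, seq_len, replace = TRUE,
                    prob = spec$background)
    id <- sprintf("pos%04d", i)
    if (stats::runif(1) <= spec$occurrence_rate) {
      inst <- vapply(seq_len(w), function(j) {
        sample(DNA_BASES, 1L, prob = spec$ppm[, j])
      }, character(1))
      off <- sample.int(seq_len - w + 1L, 1L) - 1L  # 0-based
      chars[(off + 1L):(off + w)] <- inst
      gt_id <- c(gt_id, id)
      gt_off <- c(gt_off, off)
      gt_inst <- c(gt_inst, paste(inst, collapse = ""))
    }
    positives[[i]] <- seq_record(id, paste(chars, collapse = ""), 1L)
  }
  negatives <- lapply(positives, shuffle_negative)
  records <- split_kmers(c(positives, negatives), lenk = lenk)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  list(
    records = records,
    ground_truth = data.frame(sequence_id = gt_id, offset = gt_off,
                              instance = gt_inst, stringsAsFactors = FALSE)
  )
}

#' Write a planted-motif ground truth table
#'
#' Plain TSV with columns sequence_id, offset (0-based), instance.
#'
#' @param ground_truth The \code{ground_truth} data.frame from
#'   [generate_synthetic()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.table(ground_truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a planted-motif spec from JSON
#'
#' Expected keys: \code{ppm} (4 x w matrix, rows A/C/G/T),
#' \code{occurrence_rate}, \code{background}; missing keys take the
#' [planted_motif_spec()] defaults.
#'
#' @param path JSON file.
#' @return A [planted_motif_spec()].
#' @export
read_motif_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ppm <- x$ppm
  if (!is.matrix(ppm)) {
    ppm <- matrix(as.numeric(unlist(ppm)), nrow = 4L, byrow = TRUE)
  }
  if (nrow(ppm) != 4L && ncol(ppm) == 4L) ppm <- t(ppm)
  storage.mode(ppm) <- "double"
  planted_motif_spec(
    ppm = ppm,
    occurrence_rate = if (is.null(x$occurrence_rate)) 1 else x$occurrence_rate,
    background = if (is.null(x$background)) rep(0.25, 4) else x$background
  )
}
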
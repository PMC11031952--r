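#' Construct a labeled sequence record
#'
#' A \code{seq_record} holds one fixed-length DNA sequence (default 101 bp in
#' the ATAC-seq footprint workflow), its binary bound/unbound label, and --
#' once [split_kmers()] has run -- the ordered list of k-mer occurrences that
#' turn the sequence into nodes of the heterogeneous graph.
#'
#' @param id Character scalar, sequence identifier.
#' @param sequence Character scalar over \code{A,C,G,T} (uppercased).
#' @param label Integer, 1 = positive (contains a TFBS), 0 = negative.
#' @return An object of class \code{seq_record}: a list with fields
#'   \code{id}, \code{sequence}, \code{label} and \code{kmer_occurrences}
#'   (a data.frame with columns \code{kmer} and \code{offset}, 0-based;
#'   \code{NULL} until [split_kmers()] is called).
#' @export
seq_record <- function(id, sequence, label) {
  sequence <- toupper(as.character(sequence))
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) {
    stop("label must be 0 or 1, got ", label)
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("sequence for '", id, "' contains symbols outside A/C/G/T")
  }
  structure(
    list(id = as.character(id), sequence = sequence, label = label,
         kmer_occurrences = NULL),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  nk <- if (is.null(x$kmer_occurrences)) 0L else nrow(x$kmer_occurrences)
  cat(sprintf("<seq_record %s> label=%d len=%d kmers=%d\n",
              x$id, x$label, nchar(x$sequence), nk))
  invisible(x)
}

record_labels <- function(records) {
  vapply(records, function(r) r$label, integer(1))
}

record_ids <- function(records) {
  vapply(records, function(r) r$id, character(1))
}

record_sequences <- function(records) {
  vapply(records, function(r) r$sequence, character(1))
}
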
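#' Classification metrics for TFBS prediction
#'
#' Computes the six evaluation metrics from labels and predicted
#' probabilities: precision, recall, F1, accuracy (confusion counts at the
#' 0.5 threshold), AUC (area under the ROC curve by trapezoid over all
#' distinct thresholds, which credits ties with 1/2) and PRC (area under
#' the precision-recall curve in the step-wise average-precision
#' convention). With a single class present, AUC and PRC are \code{NA} and
#' the confusion-based metrics are still computed.
#'
#' @param labels Integer 0/1 vector.
#' @param probabilities Numeric vector of the same length.
#' @param threshold Hard-label cut for the confusion matrix (default 0.5).
#' @return Object of class \code{metric_report}: list with
#'   \code{precision}, \code{recall}, \code{f1}, \code{acc}, \code{auc},
#'   \code{prc}, \code{confusion} (TP, FP, FN, TN) and \code{n_eval}.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities))
  labels <- as.integer(labels)
  yhat <- as.integer(probabilities > threshold)
  tp <- sum(labels == 1L & yhat == 1L)
  fp <- sum(labels == 0L & yhat == 1L)
  fn <- sum(labels == 1L & yhat == 0L)
  tn <- sum(labels == 0L & yhat == 0L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  acc <- (tp + tn) / length(labels)
  both <- any(labels == 1L) && any(labels == 0L)
  structure(
    list(precision = precision, recall = recall, f1 = f1, acc = acc,
         auc = if (both) roc_auc(labels, probabilities) else NA_real_,
         prc = if (both) average_precision(labels, probabilities)
               else NA_real_,
         confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
         n_eval = length(labels)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n=%d precision=%.3f recall=%.3f F1=%.3f ACC=%.3f AUC=%.3f PRC=%.3f\n",
    x$n_eval, x$precision, x$recall, x$f1, x$acc, x$auc, x$prc))
  invisible(x)
}

# Trapezoidal area under the ROC curve, sweeping all distinct score
# thresholds. Grouping tied scores into single ROC points makes the
# trapezoid equal the probability that a random positive outranks a random
# negative, ties counted 1/2.
roc_auc <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]; scores <- scores[ord]
  cuts <- cumsum(rle(scores)$lengths)
  tp <- cumsum(labels == 1L)[cuts]
  fp <- cumsum(labels == 0L)[cuts]
  tpr <- c(0, tp / sum(labels == 1L))
  fpr <- c(0, fp / sum(labels == 0L))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Step-wise average precision: sum over distinct thresholds of
# (recall increment) * (precision at that threshold).
average_precision <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]; scores <- scores[ord]
  cuts <- cumsum(rle(scores)$lengths)
  tp <- cumsum(labels == 1L)[cuts]
  prec <- tp / cuts
  rec <- tp / sum(labels == 1L)
  sum(diff(c(0, rec)) * prec)
}

#' Motif significance threshold
#'
#' The significance convention for matched motifs: a motif is significant
#' when its \code{-log10(p)} strictly exceeds \code{-log10(0.05) = 1.301},
#' i.e. p < 0.05. The p-values themselves come from external matching tools;
#' this package only applies the convention.
#'
#' @return \code{-log10(0.05)}, approximately 1.301.
#' @export
significance_threshold <- function() {
  -log10(0.05)
}

#' Flag significant motifs
#'
#' @param neg_log10_p Numeric vector of \code{-log10(p)} values.
#' @return Logical vector: strictly greater than [significance_threshold()].
#' @export
is_significant_motif <- function(neg_log10_p) {
  neg_log10_p > significance_threshold()
}

#' Write a metric report as TSV
#'
#' @param report A [compute_metrics()] result.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_metrics_tsv <- function(report, path) {
  df <- data.frame(
    metric = c("precision", "recall", "f1", "acc", "auc", "prc",
               "tp", "fp", "fn", "tn", "n_eval"),
    value = c(report$precision, report$recall, report$f1, report$acc,
              report$auc, report$prc, report$confusion[["TP"]],
              report$confusion[["FP"]], report$confusion[["FN"]],
              report$confusion[["TN"]], report$n_eval))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
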
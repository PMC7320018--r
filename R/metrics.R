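#' Confusion counts for binary TNBC predictions
#'
#' Tallies the standard 2x2 confusion table with TNBC (label 1) as the
#' positive class.
#'
#' @param truth,predicted equal-length binary vectors (1 = TNBC).
#' @return named integer vector with elements `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- check_binary_labels(truth)
  predicted <- check_binary_labels(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length")
  }
  c(tp = sum(truth == 1L & predicted == 1L),
    tn = sum(truth == 0L & predicted == 0L),
    fp = sum(truth == 0L & predicted == 1L),
    fn = sum(truth == 1L & predicted == 0L))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy = (TP + TN) / (TP + TN + FN + FP); Precision = TP / (TP + FP);
#' Recall = TP / (TP + FN); F1 = 2 * Precision * Recall /
#' (Precision + Recall). Degenerate denominators follow the usual convention:
#' precision and recall are 0 when their denominator is 0, and F1 is 0 when
#' precision + recall = 0, so a model that never predicts the positive class
#' scores 0 rather than NaN. On this unbalanced cohort the F1 score is the
#' headline metric.
#'
#' @param counts named vector from [confusion_counts()] (or any vector with
#'   `tp`, `tn`, `fp`, `fn`).
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`, all
#'   in \[0, 1\].
#' @export
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (anyNA(c(tp, tn, fp, fn)) || any(c(tp, tn, fp, fn) < 0)) {
    stop("counts must be non-negative and complete (tp, tn, fp, fn)")
  }
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated samples: total count is zero")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(accuracy = (tp + tn) / total, precision = precision,
    recall = recall, f1 = f1)
}
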
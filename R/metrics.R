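#' Confusion-matrix counts
#'
#' Tallies the standard 2x2 table for binary predictions with a declared
#' positive label.
#'
#' @param y_true,y_pred Equal-length binary label vectors.
#' @param positive_label The label counted as positive (default 1).
#' @return A list of class `"confusion_counts"` with integer `TP`, `TN`,
#'   `FP`, `FN`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(y_true, y_pred, positive_label = 1) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch: ", length(y_true), " true vs ",
         length(y_pred), " predicted labels")
  }
  labs <- unique(c(y_true, y_pred))
  if (length(labs) > 2) {
    stop("labels must be binary; found ", length(labs), " distinct values")
  }
  tp <- sum(y_true == positive_label & y_pred == positive_label)
  tn <- sum(y_true != positive_label & y_pred != positive_label)
  fp <- sum(y_true != positive_label & y_pred == positive_label)
  fn <- sum(y_true == positive_label & y_pred != positive_label)
  structure(
    list(TP = as.integer(tp), TN = as.integer(tn),
         FP = as.integer(fp), FN = as.integer(fn)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

ratio_pct <- function(num, den) {
  if (den == 0) NA_real_ else 100 * num / den
}

#' Evaluation metrics from confusion counts
#'
#' The five standard diagnostic metrics, each as a percentage:
#' accuracy `(TP+TN)/(TP+FP+FN+TN)`, sensitivity (true positive rate,
#' recall) `TP/(TP+FN)`, specificity (true negative rate) `TN/(TN+FP)`,
#' precision (positive predictive value) `TP/(TP+FP)`, and the F1 score,
#' the harmonic mean of precision and sensitivity. A metric whose
#' denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return A list of class `"metric_report"` with `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`, all in \[0, 100\] or
#'   `NA`.
#' @examples
#' compute_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0)))
#' @export
compute_metrics <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0) stop("at least one count must be positive")
  accuracy <- ratio_pct(counts$TP + counts$TN, n)
  sensitivity <- ratio_pct(counts$TP, counts$TP + counts$FN)
  specificity <- ratio_pct(counts$TN, counts$TN + counts$FP)
  precision <- ratio_pct(counts$TP, counts$TP + counts$FP)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            precision + sensitivity == 0) {
    NA_real_
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  structure(
    list(accuracy = accuracy, sensitivity = sensitivity,
         specificity = specificity, precision = precision, f1 = f1,
         counts = counts),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf(
    "accuracy %s | sensitivity %s | specificity %s | precision %s | F1 %s\n",
    fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
    fmt(x$precision), fmt(x$f1)))
  invisible(x)
}

#' Flatten a metric report to a one-row data frame
#'
#' @param report A `"metric_report"`.
#' @param ... Extra identifying columns (e.g. dataset, method, arm).
#' @return A one-row data frame with the five metrics rounded to 2
#'   decimals.
#' @export
metrics_row <- function(report, ...) {
  data.frame(...,
             accuracy = round(report$accuracy, 2),
             sensitivity = round(report$sensitivity, 2),
             specificity = round(report$specificity, 2),
             precision = round(report$precision, 2),
             f1 = round(report$f1, 2),
             stringsAsFactors = FALSE)
}
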
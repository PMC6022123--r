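#' Confusion matrix with hemiplegic as the positive class
#'
#' @param y_true,y_pred equal-length binary vectors (1 = hemiplegic,
#'   0 = normal).
#' @return A `confusion_matrix`: list with integer counts `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred) || !length(y_true)) {
    abort_hg("y_true and y_pred must be equal nonzero length",
             "hemigait_validation_error")
  }
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    abort_hg("labels must be binary 0/1", "hemigait_validation_error")
  }
  structure(
    list(tp = sum(y_true == 1L & y_pred == 1L),
         fn = sum(y_true == 1L & y_pred == 0L),
         fp = sum(y_true == 0L & y_pred == 1L),
         tn = sum(y_true == 0L & y_pred == 0L)),
    class = "confusion_matrix"
  )
}

#' @rdname confusion
#' @param tp,fn,fp,tn nonnegative counts.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_hg("counts must be nonnegative integers", "hemigait_validation_error")
  }
  structure(lapply(counts, as.integer), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FN=%d FP=%d TN=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Sensitivity, specificity, accuracy, positive predictive value
#'
#' All in percent:
#' `SE = 100 * TP / (TP + FN)`, `SP = 100 * TN / (FP + TN)`,
#' `AC = 100 * (TP + TN) / (TP + FP + TN + FN)`,
#' `PPV = 100 * TP / (TP + FP)`. A metric whose denominator is zero is
#' reported as `NA` (an explicit undefined sentinel, never silently 0 or
#' 100), so averaged cross-validation reports are not corrupted.
#'
#' @param cm a `confusion_matrix` with at least one count.
#' @return A `metrics_report`: list `se`, `sp`, `ac`, `ppv` in `[0, 100]` or
#'   `NA`.
#' @export
metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    abort_hg("metrics() expects a confusion_matrix", "hemigait_validation_error")
  }
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0L) abort_hg("empty confusion matrix", "hemigait_validation_error")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(
    list(se = rate(cm$tp, cm$tp + cm$fn),
         sp = rate(cm$tn, cm$fp + cm$tn),
         ac = rate(cm$tp + cm$tn, total),
         ppv = rate(cm$tp, cm$tp + cm$fp)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf("SE %s  SP %s  AC %s  PPV %s\n",
              fmt(x$se), fmt(x$sp), fmt(x$ac), fmt(x$ppv)))
  invisible(x)
}
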
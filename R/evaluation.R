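#' Binary confusion matrix with cancer as the positive class
#'
#' @param predicted,truth Character vectors of `"cancer"` / `"control"`.
#' @return A `confusion_matrix`: list with counts `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion(c("cancer", "control"), c("cancer", "cancer"))
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) abort("Length mismatch.")
  bad <- setdiff(unique(c(predicted, truth)), c("cancer", "control"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown label(s): %s.", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      tp = sum(predicted == "cancer" & truth == "cancer"),
      tn = sum(predicted == "control" & truth == "control"),
      fp = sum(predicted == "cancer" & truth == "control"),
      fn = sum(predicted == "control" & truth == "cancer")
    ),
    class = "confusion_matrix"
  )
}

#' Build a confusion matrix from known cell counts
#'
#' For re-deriving metrics from a published confusion matrix.
#'
#' @param tp,tn,fp,fn Non-negative cell counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP: %d; TN: %d; FP: %d; FN: %d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

# Half-up rounding to `digits` decimals (3.25 -> 3.3), the convention of
# printed diagnostic tables; R's round() is half-to-even.
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

metric_pct <- function(num, den, what, digits) {
  if (den == 0) abort(sprintf("%s undefined: empty denominator.", what))
  pct <- 100 * num / den
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Diagnostic metrics of a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and precision
#' `TP/(TP+FP)`, as percentages rounded half-up to `digits` decimals
#' (`digits = NULL` for the raw percentage).
#'
#' @param cm A `confusion_matrix`.
#' @param digits Decimals to round to (default 1); `NULL` disables
#'   rounding.
#' @return Percentage in \[0, 100\].
#' @export
sensitivity <- function(cm, digits = 1) {
  metric_pct(cm$tp, cm$tp + cm$fn, "Sensitivity", digits)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm, digits = 1) {
  metric_pct(cm$tn, cm$tn + cm$fp, "Specificity", digits)
}

#' @rdname sensitivity
#' @export
precision <- function(cm, digits = 1) {
  metric_pct(cm$tp, cm$tp + cm$fp, "Precision", digits)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly random
#' cancer score exceeds a uniformly random control score, ties counted
#' one half — identical to the trapezoidal area under the empirical ROC
#' curve. Invariant under strictly increasing score transforms.
#'
#' @param scores Numeric decision scores (larger = more cancer-like).
#' @param truth Character vector of `"cancer"` / `"control"`.
#' @return AUC as a fraction in \[0, 1\].
#' @examples
#' roc_auc(c(2, 0.5, 1, 0), c("cancer", "cancer", "control", "control"))
#' @export
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) abort("Length mismatch.")
  pos <- truth == "cancer"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present for AUC.")
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @param scores,truth As in [roc_auc()].
#' @return Tibble with `threshold`, `tpr`, `fpr`, ordered for plotting.
#' @export
roc_curve <- function(scores, truth) {
  pos <- truth == "cancer"
  if (!any(pos) || all(pos)) abort("Both classes must be present.")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble::tibble(
    threshold = th,
    tpr = vapply(th, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(th, function(t) mean(scores[!pos] >= t), numeric(1))
  )
}

#' Assemble the diagnostic report for one spectral window
#'
#' Confusion matrix, sensitivity/specificity/precision and AUC computed
#' from LOOCV decision scores (not refit in-sample scores). Percentages
#' are rounded half-up to one decimal; raw fractions are kept alongside.
#'
#' @param cv A `sers_cv` from [loocv_pca_lda()].
#' @param window Label for the spectral window (e.g. `"full"`,
#'   `"2000-2200"`).
#' @return A `diagnostic_report`.
#' @export
diagnostic_report <- function(cv, window = "full") {
  stopifnot(inherits(cv, "sers_cv"))
  r <- cv$results
  cm <- confusion(r$predicted, r$true_label)
  auc <- roc_auc(r$score, r$true_label)
  structure(
    list(
      window = window,
      confusion = cm,
      sensitivity = sensitivity(cm),
      specificity = specificity(cm),
      precision = precision(cm),
      auc = round_half_up(100 * auc, 1),
      raw = list(
        sensitivity = sensitivity(cm, digits = NULL) / 100,
        specificity = specificity(cm, digits = NULL) / 100,
        precision = precision(cm, digits = NULL) / 100,
        auc = auc,
        accuracy = (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn)
      ),
      score_basis = "loocv"
    ),
    class = "diagnostic_report"
  )
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("<diagnostic_report> window: %s (scores: %s)\n", x$window, x$score_basis))
  cat(sprintf("  AUC         %5.1f%%\n", x$auc))
  cat(sprintf("  Sensitivity %5.1f%%\n", x$sensitivity))
  cat(sprintf("  Specificity %5.1f%%\n", x$specificity))
  cat(sprintf("  Precision   %5.1f%%\n", x$precision))
  cat(sprintf("  Confusion   TP: %d; TN: %d; FP: %d; FN: %d\n",
              cm$tp, cm$tn, cm$fp, cm$fn))
  invisible(x)
}

#' @rdname diagnostic_report
#' @param x A `diagnostic_report`.
#' @param ... Unused.
#' @export
tidy.diagnostic_report <- function(x, ...) {
  tibble::tibble(
    window = x$window,
    metric = c("auc", "sensitivity", "specificity", "precision"),
    percent = c(x$auc, x$sensitivity, x$specificity, x$precision),
    fraction = with(x$raw, c(auc, sensitivity, specificity, precision))
  )
}

#' @rdname diagnostic_report
#' @export
glance.diagnostic_report <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(
    window = x$window,
    tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
    sensitivity = x$sensitivity, specificity = x$specificity,
    precision = x$precision, auc = x$auc
  )
}
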
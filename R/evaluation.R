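#' Confusion matrix from calls and truth
#'
#' "Positive" pools the target trisomies: a sample called positive for any
#' target counts once, matching overall-model reporting.
#'
#' @param calls logical (or 0/1) vector: called positive.
#' @param truth logical (or 0/1) vector: truly positive.
#' @param ids optional sample ids for both vectors; mismatched ids raise an
#'   error.
#' @param call_ids,truth_ids ids aligned with `calls` / `truth` when the
#'   two tables come from different files.
#' @return list of class `ConfusionMatrix` with `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_matrix <- function(calls, truth, ids = NULL,
                             call_ids = ids, truth_ids = ids) {
  if (!is.null(call_ids) || !is.null(truth_ids)) {
    if (is.null(call_ids) || is.null(truth_ids) ||
        length(call_ids) != length(calls) ||
        length(truth_ids) != length(truth))
      stop("ids must align with calls and truth")
    if (!setequal(call_ids, truth_ids))
      stop("sample id mismatch between calls and truth")
    truth <- truth[match(call_ids, truth_ids)]
  }
  if (length(calls) != length(truth))
    stop("calls and truth differ in length")
  calls <- as.logical(calls); truth <- as.logical(truth)
  structure(list(tp = sum(calls & truth), fn = sum(!calls & truth),
                 fp = sum(calls & !truth), tn = sum(!calls & !truth)),
            class = "ConfusionMatrix")
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  FP %d  TN %d  (n = %d)\n",
              x$tp, x$fn, x$fp, x$tn, x$tp + x$fn + x$fp + x$tn))
  invisible(x)
}

#' Round half-up to a fixed number of decimals
#'
#' Reporting convention for percentages: ties round away from zero
#' (`round()` in base R rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  trunc(x * s + 0.5 * sign(x) + 1e-9 * sign(x)) / s
}

#' Confusion-matrix metric with a 95% normal-approximation interval
#'
#' The point estimate is the relevant proportion; the interval is the Wald
#' interval `p +/- 1.96 * sqrt(p (1 - p) / n)` on the proportion scale with
#' `n` the metric's denominator, capped to \[0, 100\] after conversion to
#' percent and rounded half-up to 2 decimals (so a proportion of 1 reports
#' as 100 (100-100)).
#'
#' @param cm a `ConfusionMatrix`.
#' @param metric one of `"sensitivity"`, `"specificity"`, `"ppv"`, `"npv"`.
#' @return list of class `MetricWithCI`: `estimate`, `ci_low`, `ci_high`
#'   (percent, 2 decimals).
#' @export
metric_with_ci <- function(cm, metric = c("sensitivity", "specificity",
                                          "ppv", "npv")) {
  metric <- match.arg(metric)
  num_den <- switch(metric,
                    sensitivity = c(cm$tp, cm$tp + cm$fn),
                    specificity = c(cm$tn, cm$tn + cm$fp),
                    ppv = c(cm$tp, cm$tp + cm$fp),
                    npv = c(cm$tn, cm$tn + cm$fn))
  if (num_den[2] == 0) stop("undefined metric: zero denominator for ", metric)
  p <- num_den[1] / num_den[2]
  half <- 1.96 * sqrt(p * (1 - p) / num_den[2])
  structure(list(
    estimate = round_half_up(100 * p),
    ci_low = round_half_up(max(0, 100 * (p - half))),
    ci_high = round_half_up(min(100, 100 * (p + half)))),
    class = "MetricWithCI")
}

#' @export
print.MetricWithCI <- function(x, ...) {
  cat(sprintf("%.2f (%.2f-%.2f)\n", x$estimate, x$ci_low, x$ci_high))
  invisible(x)
}

#' Full metric report for a set of methods
#'
#' @param cms named list of `ConfusionMatrix` objects (one per method).
#' @return `data.table`: method, counts, and the four metrics with their
#'   interval bounds.
#' @export
metric_report <- function(cms) {
  rows <- lapply(names(cms), function(nm) {
    cm <- cms[[nm]]
    out <- list(method = nm, tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn)
    for (m in c("sensitivity", "specificity", "ppv", "npv")) {
      mc <- metric_with_ci(cm, m)
      out[[m]] <- mc$estimate
      out[[paste0(m, "_lo")]] <- mc$ci_low
      out[[paste0(m, "_hi")]] <- mc$ci_high
    }
    as.data.table(out)
  })
  rbindlist(rows)
}

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney) formulation; ties get half weight.
#'
#' @param p predicted probabilities or scores.
#' @param y binary 0/1 truth.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(p, y) {
  y <- as.integer(as.logical(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
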
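#' Confusion counts
#'
#' @param labels Predicted binary labels (logical or 0/1).
#' @param truth True binary labels, same length.
#' @return Object of class `"confusion"`: list `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, truth) {
  if (length(labels) != length(truth)) stop("length mismatch")
  if (length(labels) == 0) stop("empty input")
  labels <- as.logical(labels); truth <- as.logical(truth)
  structure(list(tp = sum(labels & truth), fp = sum(labels & !truth),
                 tn = sum(!labels & !truth), fn = sum(!labels & truth)),
            class = "confusion")
}

#' Diagnostic-accuracy point estimates from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive values, positive and negative likelihood ratios
#' `sens/(1-spec)` and `(1-sens)/spec`, and Youden's index
#' `sensitivity + specificity - 1`. Ratios with zero denominators are
#' reported as `NaN` (flagged in `undefined`), never as an error.
#'
#' @param c A `confusion` object.
#' @return List of the point estimates plus an `undefined` character
#'   vector naming any undefined ratios.
#' @export
rates <- function(c) {
  n <- c$tp + c$fp + c$tn + c$fn
  if (n == 0) stop("empty confusion counts")
  div <- function(a, b) if (b == 0) NaN else a / b
  sens <- div(c$tp, c$tp + c$fn)
  spec <- div(c$tn, c$tn + c$fp)
  out <- list(
    sensitivity = sens, specificity = spec,
    ppv = div(c$tp, c$tp + c$fp), npv = div(c$tn, c$tn + c$fn),
    plr = if (!is.nan(spec) && spec == 1) NaN else sens / (1 - spec),
    nlr = if (!is.nan(spec) && spec == 0) NaN else (1 - sens) / spec,
    youden = sens + spec - 1
  )
  out$undefined <- names(out)[vapply(out[1:7], is.nan, logical(1))]
  out
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC is the Mann-Whitney probability that a random positive scores
#' above a random negative, ties counted half. The 95% CI is DeLong's.
#'
#' @param scores Real-valued classifier scores.
#' @param truth Binary truth with both classes present.
#' @return List `auc`, `ci` (length 2).
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2) stop("`truth` must contain both classes")
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]),
    error = function(e) c(NA_real_, NA_real_))
  list(auc = as.numeric(pROC::auc(r)), ci = ci)
}

#' Confidence intervals for confusion-based metrics
#'
#' Proportions (sensitivity, specificity, predictive values) get exact
#' Clopper-Pearson binomial intervals; likelihood ratios get the standard
#' log-method interval. Zero cells yield degenerate/one-sided intervals,
#' flagged via `NaN` bounds where undefined.
#'
#' @param c A `confusion` object.
#' @param level Confidence level (default 0.95).
#' @return Named list of length-2 intervals.
#' @export
metric_cis <- function(c, level = 0.95) {
  al <- 1 - level
  cp <- function(x, n) {
    if (n == 0) return(c(NaN, NaN))
    lo <- if (x == 0) 0 else stats::qbeta(al / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - al / 2, x + 1, n - x)
    c(lo, hi)
  }
  z <- stats::qnorm(1 - al / 2)
  lr_ci <- function(lr, se_terms) {
    if (!is.finite(lr) || lr <= 0) return(c(NaN, NaN))
    se <- sqrt(sum(se_terms))
    exp(log(lr) + c(-z, z) * se)
  }
  r <- rates(c)
  list(
    sensitivity = cp(c$tp, c$tp + c$fn),
    specificity = cp(c$tn, c$tn + c$fp),
    ppv = cp(c$tp, c$tp + c$fp),
    npv = cp(c$tn, c$tn + c$fn),
    plr = lr_ci(r$plr, c(1 / c$tp - 1 / (c$tp + c$fn),
                         1 / c$fp - 1 / (c$fp + c$tn))),
    nlr = lr_ci(r$nlr, c(1 / c$fn - 1 / (c$tp + c$fn),
                         1 / c$tn - 1 / (c$fp + c$tn)))
  )
}

#' One evaluation row: all metrics with confidence intervals
#'
#' Assembles the report shape used throughout: AUC, sensitivity,
#' specificity, +LR, -LR, +PV, -PV (each with 95% CI) and Youden's index.
#'
#' @param labels Predicted binary labels.
#' @param scores Real-valued scores for the ROC (may be `NULL` to skip AUC).
#' @param truth Binary truth.
#' @return A one-row data frame.
#' @export
metrics_report <- function(labels, scores, truth) {
  cc <- confusion(labels, truth)
  r <- rates(cc)
  ci <- metric_cis(cc)
  auc <- if (is.null(scores) || length(unique(as.logical(truth))) < 2) {
    list(auc = NA_real_, ci = c(NA_real_, NA_real_))
  } else roc_auc(scores, truth)
  data.frame(
    auc = auc$auc, auc_lo = auc$ci[1], auc_hi = auc$ci[2],
    sensitivity = r$sensitivity, sens_lo = ci$sensitivity[1],
    sens_hi = ci$sensitivity[2],
    specificity = r$specificity, spec_lo = ci$specificity[1],
    spec_hi = ci$specificity[2],
    plr = r$plr, plr_lo = ci$plr[1], plr_hi = ci$plr[2],
    nlr = r$nlr, nlr_lo = ci$nlr[1], nlr_hi = ci$nlr[2],
    ppv = r$ppv, ppv_lo = ci$ppv[1], ppv_hi = ci$ppv[2],
    npv = r$npv, npv_lo = ci$npv[1], npv_hi = ci$npv[2],
    youden = r$youden
  )
}
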
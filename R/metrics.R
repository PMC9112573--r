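#' Mean absolute error
#'
#' @param y Observed values.
#' @param yhat Predictions of the same length.
#' @return Mean of `|y - yhat|`.
#' @export
#' @examples
#' mae(c(0, 10), c(2, 6))  # 3
mae <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat)) {
    abort("`y` and `yhat` must be non-empty and of equal length.",
          class = "metastackr_invalid_argument")
  }
  mean(abs(y - yhat))
}

#' Area under the receiver operating characteristic curve
#'
#' Computed in the Mann--Whitney form: the fraction of (positive, negative)
#' pairs in which the positive case receives the higher score, counting tied
#' scores as one half. Equivalent to integrating the ROC curve, and invariant
#' to any strictly monotone transform of the scores.
#'
#' @param y Binary 0/1 outcomes.
#' @param p Scores (need not be probabilities).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 0.75
auc <- function(y, p) {
  if (length(y) != length(p) || length(y) == 0L) {
    abort("`y` and `p` must be non-empty and of equal length.",
          class = "metastackr_invalid_argument")
  }
  if (!all(y %in% c(0, 1))) {
    abort("`y` must be 0/1.", class = "metastackr_invalid_argument")
  }
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC undefined: both outcome classes must be present.",
          class = "metastackr_undefined_auc")
  }
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration-in-the-large
#'
#' Compares the average predicted event probability with the observed event
#' rate; no recalibration is performed. A nonzero difference means the model
#' over- (positive) or under-estimates (negative) risk on average.
#'
#' @param y Binary 0/1 outcomes.
#' @param p Predicted probabilities in \[0, 1\].
#' @return Tibble with `mean_pred`, `event_rate`, `difference`
#'   (= mean_pred - event_rate).
#' @export
calibration_in_the_large <- function(y, p) {
  if (length(y) != length(p) || length(y) == 0L) {
    abort("`y` and `p` must be non-empty and of equal length.",
          class = "metastackr_invalid_argument")
  }
  if (!all(y %in% c(0, 1)) || any(p < 0 | p > 1)) {
    abort("`y` must be 0/1 and `p` in [0, 1].",
          class = "metastackr_invalid_argument")
  }
  tibble(mean_pred = mean(p), event_rate = mean(y),
         difference = mean(p) - mean(y))
}

#' Baseline-adjusted percent change in AUC
#'
#' Percent change computed after subtracting the chance level 0.5 from both
#' AUCs, so that gains are measured relative to the discrimination actually
#' achieved above chance:
#' \eqn{100 \times [(AUC_{new} - 0.5) - (AUC_{ref} - 0.5)] / (AUC_{ref} - 0.5)}.
#'
#' @param auc_ref Reference AUC (must exceed 0.5).
#' @param auc_new Comparison AUC.
#' @return Percent change (positive = improvement).
#' @export
#' @examples
#' adjusted_auc_pct_change(0.598, 0.604)  # +6.12
adjusted_auc_pct_change <- function(auc_ref, auc_new) {
  if (!is.numeric(auc_ref) || auc_ref <= 0.5) {
    abort("`auc_ref` must exceed the 0.5 chance level.",
          class = "metastackr_undefined_change")
  }
  100 * (auc_new - auc_ref) / (auc_ref - 0.5)
}

#' Plain relative percent change in MAE
#'
#' MAE improvements are reported as an ordinary relative change (no baseline
#' subtraction): \eqn{100 \times (MAE_{ref} - MAE_{new}) / MAE_{ref}},
#' positive when the new model has the smaller error.
#'
#' @param mae_ref Reference MAE (> 0).
#' @param mae_new Comparison MAE.
#' @return Percent change (positive = improvement).
#' @export
#' @examples
#' pct_change_mae(4.63, 4.52)  # +2.38
pct_change_mae <- function(mae_ref, mae_new) {
  if (!is.numeric(mae_ref) || mae_ref <= 0) {
    abort("`mae_ref` must be positive.",
          class = "metastackr_invalid_argument")
  }
  100 * (mae_ref - mae_new) / mae_ref
}

#' Percentile bootstrap confidence interval
#'
#' Empirical percentiles of replicate estimates under the linear-interpolation
#' quantile convention (`stats::quantile` type 7), fixed so interval endpoints
#' are bit-reproducible.
#'
#' @param values Replicate estimates (>= 2).
#' @param lo,hi Percentile bounds (defaults 2.5 and 97.5).
#' @return Named numeric vector `c(low, high)`.
#' @export
#' @examples
#' percentile_ci(0:100)  # c(low = 2.5, high = 97.5)
percentile_ci <- function(values, lo = 2.5, hi = 97.5) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    abort("Need at least 2 replicate values.",
          class = "metastackr_invalid_argument")
  }
  q <- stats::quantile(values, probs = c(lo, hi) / 100, type = 7,
                       names = FALSE)
  c(low = q[1L], high = q[2L])
}
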
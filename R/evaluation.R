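#' Normalized root mean squared error
#'
#' RMSE divided by the span of the volunteer's measured torque: maximum
#' flexion torque plus the absolute value of the maximum extension torque
#' (extension is negative by convention). The maxima refer to the torques
#' the volunteer exerted over the session; when evaluating on a narrow test
#' window, pass them explicitly (they default to the extrema of `measured`).
#'
#' @param estimated,measured Torque series of equal length, N·m.
#' @param tau_flex,tau_ext Maximum flexion torque (positive) and maximum
#'   extension torque (negative, taken as its absolute value) defining the
#'   normalization span.
#' @return NRMSE as a fraction (multiply by 100 for percent).
#' @export
nrmse <- function(estimated, measured, tau_flex = max(measured),
                  tau_ext = min(measured)) {
  if (length(estimated) != length(measured) || !length(measured))
    stop("series must be non-empty and of equal length")
  denom <- tau_flex + abs(tau_ext)
  if (denom <= 0) stop("measured torque range is zero; NRMSE undefined")
  sqrt(mean((estimated - measured)^2)) / denom
}

#' Coefficient of determination
#'
#' R² = 1 - SSE/SST against the mean of the measured series; can be negative
#' for fits worse than the mean predictor.
#'
#' @param estimated,measured Torque series of equal length.
#' @return R², dimensionless.
#' @export
r_squared <- function(estimated, measured) {
  if (length(estimated) != length(measured) || !length(measured))
    stop("series must be non-empty and of equal length")
  sst <- sum((measured - mean(measured))^2)
  if (sst == 0) stop("measured series is constant; R-squared undefined")
  1 - sum((estimated - measured)^2) / sst
}

#' Adjusted coefficient of determination
#'
#' Ra² = 1 - (n - 1)/(n - k - 1) * (1 - R²), penalizing R² for the number of
#' SEMG channels k used to train the model.
#'
#' @param r2 R² value.
#' @param n Sample count for the degrees-of-freedom correction.
#' @param k Number of SEMG channels used for training.
#' @return Adjusted R².
#' @export
adjusted_r_squared <- function(r2, n, k) {
  if (n <= k + 1) stop("need n > k + 1 for the adjustment")
  1 - (n - 1) / (n - k - 1) * (1 - r2)
}

#' Relative change between two metric values
#'
#' Percent mode reports 100·(after - before)/before rounded half-up to an
#' integer; fold mode reports (after - before)/before to 2 decimals. This is
#' the reporting granularity used for cross-condition degradation summaries
#' ("Ra² decreased 34%", "NRMSE increased 2.50 times").
#'
#' @param before,after Metric values; `before` must be nonzero.
#' @param mode `"percent"` or `"fold"`.
#' @return Rounded relative change.
#' @export
relative_change <- function(before, after, mode = c("percent", "fold")) {
  mode <- match.arg(mode)
  if (before == 0) stop("relative change undefined for before = 0")
  rel <- (after - before) / before
  if (mode == "percent") round_half_up(100 * rel) else round_half_up(rel, 2)
}

#' One-way analysis of variance across models
#'
#' Classical fixed-effects one-way ANOVA: F = MSB/MSW with (g - 1,
#' N - g) degrees of freedom, used to test whether per-subject metric values
#' differ in mean across models or conditions.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return List with `F` and `p`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (any(lengths(groups) < 2))
    stop("each group needs at least two values")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  f <- as.numeric(fit$statistic)
  p <- as.numeric(fit$p.value)
  if (is.nan(f)) { # zero between-group variance
    f <- 0
    p <- 1
  }
  list(F = f, p = p)
}

#' Evaluate an estimated torque series against measurements
#'
#' Bundles the three accuracy metrics with the sample and channel counts
#' used in the adjustment.
#'
#' @param estimated,measured Torque series (typically at the decimated test
#'   samples).
#' @param k Number of SEMG channels used to train the model.
#' @param tau_flex,tau_ext Session-level torque extrema for the NRMSE span
#'   (default: extrema of `measured`).
#' @param n_adjust Sample count for the degrees-of-freedom correction of
#'   adjusted R² — the number of samples the model was fitted on (default:
#'   the test count, for self-contained use).
#' @return A list of class `evaluation_result`: `nrmse` (fraction), `r2`,
#'   `ra2`, `n`, `k`, `tau_flex_max`, `tau_ext_max`.
#' @export
evaluate_estimate <- function(estimated, measured, k,
                              tau_flex = max(measured),
                              tau_ext = min(measured),
                              n_adjust = length(measured)) {
  r2 <- r_squared(estimated, measured)
  structure(list(nrmse = nrmse(estimated, measured, tau_flex, tau_ext),
                 r2 = r2,
                 ra2 = adjusted_r_squared(r2, n_adjust, k),
                 n = length(measured), k = k,
                 tau_flex_max = tau_flex,
                 tau_ext_max = tau_ext),
            class = "evaluation_result")
}
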
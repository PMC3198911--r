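#' Published cohort summary statistics of the original wrist-torque study
#'
#' Cohort means and standard deviations (NRMSE in percent, adjusted R²)
#' reported by the human-subject study this package's pipeline reimplements:
#' six models under the channel-subset conditions (`8ch`, `5ch`, `2ch`),
#' the training-fraction conditions (`train25`, `train90`), the
#' cross-session conditions (`after1h`, `after24h`) and the posture
#' condition (`supinated`). The raw per-volunteer data were never deposited,
#' so these printed summary statistics are the only numeric anchor: they are
#' used as inputs to the relative-change reporting arithmetic, not as
#' quantities this package recomputes.
#'
#' @return Data.frame with `model`, `condition`, `nrmse_mean_pct`,
#'   `nrmse_sd_pct`, `ra2_mean`, `ra2_sd`.
#' @export
reported_means <- function() {
  read.csv(system.file("extdata", "reported_cohort_means.csv",
                       package = "semgtorque"),
           stringsAsFactors = FALSE)
}

#' Derived relative-change statistics from the published summary tables
#'
#' Recomputes, per model, the degradation/improvement statistics that the
#' original study quotes as percentages and fold changes, from its printed
#' cohort means: training-size gains (25% -> 90% training), one-hour
#' cross-session degradation (same-session 8-channel baseline -> after 1 h)
#' and posture-change degradation (baseline -> supinated, NRMSE as fold
#' change, Ra² as percent).
#'
#' @return Data.frame with `model`, `comparison`, `metric`, `mode`,
#'   `change`.
#' @export
reported_derived_changes <- function() {
  rep <- reported_means()
  models <- c("PBM", "OLS", "RLS", "SVM", "ANN", "LWPR")
  get <- function(m, cond, col) rep[rep$model == m & rep$condition == cond,
                                    col]
  rows <- list()
  add <- function(model, comparison, metric, mode, change)
    rows[[length(rows) + 1]] <<- data.frame(model = model,
                                            comparison = comparison,
                                            metric = metric, mode = mode,
                                            change = change,
                                            stringsAsFactors = FALSE)
  for (m in models) {
    add(m, "train25_to_train90", "ra2", "percent",
        relative_change(get(m, "train25", "ra2_mean"),
                        get(m, "train90", "ra2_mean"), "percent"))
    add(m, "train25_to_train90", "nrmse", "percent",
        relative_change(get(m, "train25", "nrmse_mean_pct"),
                        get(m, "train90", "nrmse_mean_pct"), "percent"))
    add(m, "baseline_to_after1h", "ra2", "percent",
        relative_change(get(m, "8ch", "ra2_mean"),
                        get(m, "after1h", "ra2_mean"), "percent"))
    add(m, "baseline_to_after1h", "nrmse", "percent",
        relative_change(get(m, "8ch", "nrmse_mean_pct"),
                        get(m, "after1h", "nrmse_mean_pct"), "percent"))
    add(m, "baseline_to_supinated", "nrmse", "fold",
        relative_change(get(m, "8ch", "nrmse_mean_pct"),
                        get(m, "supinated", "nrmse_mean_pct"), "fold"))
  }
  do.call(rbind, rows)
}
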
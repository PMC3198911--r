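#' Fit any of the six torque estimators behind one contract
#'
#' Uniform surface over the physiological model (`"pbm"`), the linear models
#' (`"ols"`, `"rls"`) and the machine-learning regressors (`"svr"`, `"ann"`,
#' `"lwpr"`). The physiological model's activation recursion runs over the
#' full-rate envelopes (the 1 kHz timebase is needed to resolve the
#' electromechanical delay) with the calibration objective evaluated only at
#' the decimated training samples; all other models are fitted directly on
#' the decimated envelope matrix at those samples.
#'
#' @param kind One of `"pbm"`, `"ols"`, `"rls"`, `"svr"`, `"ann"`, `"lwpr"`.
#' @param train A full-rate `processed_recording` (already restricted to the
#'   channel subset in use).
#' @param resample_k Decimation step (default 100).
#' @param seed Seed for the stochastic fitters (GA, SVR/LWPR folds, ANN
#'   restarts).
#' @param tab Physiological table (used by `"pbm"`).
#' @param sigma_pcsa Optional SigmaPCSA redistribution for reduced channel
#'   sets (`"pbm"`).
#' @param ga [ga_config()] for `"pbm"` (its `seed` is overridden by `seed`).
#' @param lambda Regularization parameter for `"rls"`.
#' @param est_config Optional [estimator_config()] for the ML kinds; built
#'   from defaults when NULL (`kind` and `seed` are always overridden).
#' @param idx Optional full-rate sample indices of the training samples
#'   (supports non-contiguous splits); default every `resample_k`-th sample.
#' @return A list of class `torque_model`.
#' @export
fit_torque_model <- function(kind, train, resample_k = 100, seed = 1,
                             tab = muscle_table(), sigma_pcsa = NULL,
                             ga = ga_config(), lambda = 0.01,
                             est_config = NULL, idx = NULL) {
  kind <- match.arg(kind, c("pbm", "ols", "rls", "svr", "ann", "lwpr"))
  stopifnot(inherits(train, "processed_recording"))
  channels <- colnames(train$envelopes)
  n <- nrow(train$envelopes)
  if (is.null(idx)) idx <- seq.int(min(resample_k, n), n, by = resample_k)
  idx <- as.integer(idx)
  fit <- if (kind == "pbm") {
    ga$seed <- as.integer(seed)
    calibrate_pbm(train, tab, ga, resample_k, sigma_pcsa, idx = idx)
  } else {
    problem <- regression_problem(train$envelopes[idx, , drop = FALSE],
                                  train$torque[idx])
    switch(kind,
           ols = ols_fit(problem),
           rls = rls_fit(problem, lambda),
           {
             if (is.null(est_config))
               est_config <- estimator_config(kind, seed = seed)
             est_config$kind <- kind
             est_config$seed <- as.integer(seed)
             fit_estimator(problem, est_config)
           })
  }
  structure(list(kind = kind, fit = fit, channels = channels,
                 resample_k = resample_k, seed = seed,
                 train_n = length(idx)),
            class = "torque_model")
}

#' Predict decimated torque from a fitted torque model
#'
#' @param model A `torque_model` from [fit_torque_model()].
#' @param test A full-rate `processed_recording` containing the model's
#'   channels.
#' @param idx Optional full-rate sample indices at which to predict
#'   (default: every `resample_k`-th sample). The physiological model's
#'   recursion always runs over the full series.
#' @return List with `estimated` and `measured` torque at those samples and
#'   `k` (channel count).
#' @export
predict_torque <- function(model, test, idx = NULL) {
  stopifnot(inherits(model, "torque_model"),
            inherits(test, "processed_recording"))
  test <- subset_channels(test, model$channels)
  k <- model$resample_k
  n <- nrow(test$envelopes)
  if (is.null(idx)) idx <- seq.int(min(k, n), n, by = k)
  idx <- as.integer(idx)
  est <- if (model$kind == "pbm") {
    forward_pbm(test, model$fit$params, idx = idx)
  } else {
    design <- test$envelopes[idx, , drop = FALSE]
    if (model$kind %in% c("ols", "rls")) linear_predict(model$fit, design)
    else estimator_predict(model$fit, design)
  }
  list(estimated = est, measured = test$torque[idx],
       k = length(model$channels))
}

#' Evaluate a fitted torque model on a test segment
#'
#' @param model A `torque_model`.
#' @param test Full-rate `processed_recording`.
#' @param range_from `processed_recording` whose torque extrema define the
#'   NRMSE normalization span (the volunteer's session-level maximum flexion
#'   and extension torques); defaults to `test` itself. Pass the full
#'   session recording when `test` covers a narrow held-out window.
#' @param idx Optional full-rate sample indices of the test samples.
#' @return An `evaluation_result`.
#' @export
evaluate_model <- function(model, test, range_from = test, idx = NULL) {
  p <- predict_torque(model, test, idx = idx)
  evaluate_estimate(p$estimated, p$measured, p$k,
                    tau_flex = max(range_from$torque),
                    tau_ext = min(range_from$torque),
                    n_adjust = model$train_n)
}
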
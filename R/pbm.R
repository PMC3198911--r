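#' Discrete recursive activation filter
#'
#' Maps a processed SEMG envelope e(t) into neural activation drive u(t)
#' through the discretized critically-damped twitch model
#' u(t) = alpha·e(t - d) - beta1·u(t-1) - beta2·u(t-2), with the
#' electromechanical delay d rounded to whole samples and u = 0 before the
#' first delayed sample. The parameterization beta1 = C1 + C2,
#' beta2 = C1·C2, alpha = 1 + beta1 + beta2 guarantees stability
#' (|C1|, |C2| < 1) and exact unit DC gain.
#'
#' @param e Envelope series, values in \[0, 1\].
#' @param params An [activation_params()] object.
#' @param sample_rate_hz Sampling rate of `e`, Hz.
#' @return Activation drive series u, same length as `e`.
#' @export
recursive_filter <- function(e, params, sample_rate_hz = 1000) {
  stopifnot(inherits(params, "activation_params"))
  d <- as.integer(round(params$d_ms / 1000 * sample_rate_hz))
  n <- length(e)
  shifted <- if (d >= n) numeric(n) else c(numeric(d), e[seq_len(n - d)])
  as.numeric(stats::filter(params$alpha * shifted,
                           c(-params$beta1, -params$beta2),
                           method = "recursive"))
}

#' Nonlinear activation shaping
#'
#' a(u) = (exp(A·u) - 1) / (exp(A) - 1) for A < 0; the A = 0 case is the
#' analytic limit a = u. Maps \[0, 1\] onto \[0, 1\] monotonically, with
#' stronger-than-linear rise at low drive for more negative A (exponential
#' recruitment of motor-unit firing at low force).
#'
#' @param u Drive series in \[0, 1\].
#' @param A Shape factor in \[-3, 0\].
#' @param clamp Clip `u` into \[0, 1\] first (used by the forward model,
#'   where filter transients may overshoot marginally). Default FALSE.
#' @return Activation series in \[0, 1\].
#' @export
activation_nonlinearity <- function(u, A, clamp = FALSE) {
  if (!(A >= -3 && A <= 0)) stop("A must lie in [-3, 0]")
  if (clamp) u <- pmin(pmax(u, 0), 1)
  if (any(u < -1e-9 | u > 1 + 1e-9))
    stop("u must lie in [0, 1]")
  if (A > -1e-12) return(u)
  expm1(A * u) / expm1(A)
}

#' Isometric joint torque from per-channel activations
#'
#' F_j = Fmax_j·a_j, tau_j = F_j·MA_j, and the wrist torque is the
#' PCSA-weighted sum tau_e = sum_j (SigmaPCSA_j / PCSA_j)·tau_j, so each
#' surface channel stands in for the deep muscles it represents. Flexor
#' channels (positive moment arm) contribute positive torque, extensors
#' negative.
#'
#' @param a Matrix of activations, samples x channels, in \[0, 1\].
#' @param params A [pbm_parameters()] object with one muscle per channel.
#' @return Torque series, N·m.
#' @export
joint_torque <- function(a, params) {
  stopifnot(inherits(params, "pbm_parameters"))
  a <- as.matrix(a)
  if (ncol(a) != length(params$muscles))
    stop("activation channel count (", ncol(a),
         ") does not match muscle count (", length(params$muscles), ")")
  w <- vapply(params$muscles,
              function(m) m$sigma_pcsa_cm2 / m$pcsa_cm2 * m$fmax_N * m$ma_m,
              numeric(1))
  as.numeric(a %*% w)
}

#' Two-channel (one flexor, one extensor) torque
#'
#' Reduced model in which the single recorded flexor carries the pooled PCSA
#' of all flexors and the single extensor the pooled PCSA of all extensors:
#' tau_e = (SigmaPCSA_flexors / PCSA_flexor)·tau_flexor +
#' (SigmaPCSA_extensors / PCSA_extensor)·tau_extensor.
#'
#' @param a_flexor,a_extensor Activation series of the recorded flexor and
#'   extensor, in \[0, 1\].
#' @param params A [pbm_parameters()] object with exactly two muscles, one
#'   flexor then one extensor (any order).
#' @param pcsa_table Cohort PCSA table ([muscle_table()]) used to pool the
#'   role-wise PCSA sums.
#' @return Torque series, N·m.
#' @export
two_channel_torque <- function(a_flexor, a_extensor, params,
                               pcsa_table = muscle_table()) {
  stopifnot(inherits(params, "pbm_parameters"))
  roles <- vapply(params$muscles, `[[`, character(1), "role")
  if (length(params$muscles) != 2L || !all(sort(roles) == c("extensor", "flexor")))
    stop("exactly one flexor and one extensor muscle required")
  fi <- which(roles == "flexor")
  ei <- which(roles == "extensor")
  names <- vapply(params$muscles, `[[`, character(1), "name")
  sigma <- redistribute_sigma_pcsa(pcsa_table, c(names[fi], names[ei]))
  muscles <- params$muscles[c(fi, ei)]
  muscles[[1]]$sigma_pcsa_cm2 <- sigma[1]
  muscles[[2]]$sigma_pcsa_cm2 <- sigma[2]
  joint_torque(cbind(a_flexor, a_extensor),
               pbm_parameters(params$activation, muscles))
}

# Per-channel torque weights (SigmaPCSA/PCSA * Fmax * MA), N*m per unit
# activation.
pbm_weights <- function(params) {
  vapply(params$muscles,
         function(m) m$sigma_pcsa_cm2 / m$pcsa_cm2 * m$fmax_N * m$ma_m,
         numeric(1))
}

#' Forward physiological torque model
#'
#' Composition recursive_filter -> activation_nonlinearity -> joint_torque
#' per channel, run at the full (pre-decimation) sample rate so the 10–100 ms
#' electromechanical delay is resolvable in whole samples. Torque can be
#' returned at a subset of sample indices (`idx`), which is how decimated
#' training/test targets are produced after forward modeling.
#'
#' @param processed A `processed_recording` (or plain envelope matrix via
#'   `envelopes`/`sample_rate_hz`).
#' @param params A [pbm_parameters()] object, one muscle per channel.
#' @param idx Strictly increasing 1-based sample indices at which torque is
#'   evaluated; default all samples.
#' @return Torque series (length `length(idx)`), N·m.
#' @export
forward_pbm <- function(processed, params, idx = NULL) {
  stopifnot(inherits(params, "pbm_parameters"))
  if (inherits(processed, "processed_recording")) {
    env <- processed$envelopes
    fs <- processed$sample_rate_hz
  } else {
    env <- as.matrix(processed$envelopes)
    fs <- processed$sample_rate_hz
  }
  if (ncol(env) != length(params$muscles))
    stop("channel count does not match muscle count")
  if (is.null(idx)) idx <- seq_len(nrow(env))
  act <- params$activation
  d <- as.integer(round(act$d_ms / 1000 * fs))
  pbm_forward_core(env, as.integer(idx), d, act$alpha, act$beta1, act$beta2,
                   act$A, pbm_weights(params))
}
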
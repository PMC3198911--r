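#' Processing configuration
#'
#' Settings for the SEMG conditioning chain: high-pass cutoff for motion
#' artefact removal, low-pass cutoff for the linear envelope, Butterworth
#' design order (applied forward and backward, so the effective magnitude
#' response is the design squared), decimation step, reflective padding
#' factor, and whether supinated-session torque is sign-flipped at load so
#' flexion is always positive internally.
#'
#' @param highpass_hz High-pass cutoff, Hz. Default 30.
#' @param lowpass_hz Low-pass (envelope) cutoff, Hz. Default 6.
#' @param order Butterworth design order per pass. Default 4.
#' @param resample_k Decimation step (every k-th sample). Default 100.
#' @param pad_factor Reflective pad length as a multiple of the filter order.
#' @param flip_supinated_torque Flip torque sign for supinated recordings.
#' @return A list of class `processing_config`.
#' @export
processing_config <- function(highpass_hz = 30, lowpass_hz = 6, order = 4,
                              resample_k = 100, pad_factor = 3,
                              flip_supinated_torque = TRUE) {
  stopifnot(highpass_hz > 0, lowpass_hz > 0, order >= 1, resample_k >= 1,
            pad_factor >= 1)
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 order = as.integer(order),
                 resample_k = as.integer(resample_k),
                 pad_factor = as.integer(pad_factor),
                 flip_supinated_torque = isTRUE(flip_supinated_torque)),
            class = "processing_config")
}

#' Read a processing configuration from YAML
#'
#' Recognized keys: `highpass_hz`, `lowpass_hz`, `order`, `resample_k`,
#' `pad_factor`, `flip_supinated_torque`; missing keys take the defaults of
#' [processing_config()].
#'
#' @param path YAML file path.
#' @return A `processing_config`.
#' @export
read_processing_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(processing_config,
          vals[intersect(names(vals), names(formals(processing_config)))])
}

#' Remove the DC offset of a signal
#'
#' @param signal Numeric series.
#' @return The series minus its mean.
#' @export
remove_dc <- function(signal) {
  if (length(signal) < 1L) stop("signal must be non-empty")
  signal - mean(signal)
}

# Steady-state initial filter state (per unit step input) for direct form II
# transposed, so edge transients of a one-sided pass are minimized.
butter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  n <- nf - 1
  comp <- matrix(0, n, n)          # companion matrix of a, transposed
  comp[1, ] <- -a[-1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(comp), B)
}

# One zero-phase (forward-backward) pass with odd reflective padding.
filtfilt_reflect <- function(b, a, x, pad) {
  n <- length(x)
  if (n <= pad)
    stop("series too short for the padding scheme (need length > ",
         pad, " samples)")
  zi <- butter_zi(b, a)
  ext <- c(2 * x[1] - x[(pad + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_filter_core(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_core(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth filter
#'
#' Designs an `order`-th order Butterworth filter and applies it forward and
#' backward ("zero-lag"), with odd reflective padding at both ends to
#' suppress edge transients. The pad length is `pad_factor * order` samples,
#' enlarged to two periods of the cutoff frequency when that is longer (the
#' transient of a low cutoff at a high sampling rate spans many samples).
#' The bidirectional application squares the design's magnitude response and
#' cancels its phase.
#'
#' @param signal Numeric series.
#' @param cutoff_hz Cutoff frequency in Hz; must be below Nyquist.
#' @param kind `"highpass"` or `"lowpass"`.
#' @param order Design order per pass (default 4).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param pad_factor Reflective pad length as a multiple of `order`.
#' @return Filtered series, same length as the input.
#' @export
zero_lag_butterworth <- function(signal, cutoff_hz,
                                 kind = c("highpass", "lowpass"),
                                 order = 4, sample_rate_hz = 1000,
                                 pad_factor = 3) {
  kind <- match.arg(kind)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 ||
      cutoff_hz >= sample_rate_hz / 2)
    stop("cutoff_hz must lie strictly between 0 and Nyquist (",
         sample_rate_hz / 2, " Hz)")
  bt <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2),
                       type = if (kind == "highpass") "high" else "low")
  pad <- max(pad_factor * order, ceiling(2 * sample_rate_hz / cutoff_hz))
  filtfilt_reflect(bt$b, bt$a, signal, pad = pad)
}

#' Full-wave rectify and normalize a channel
#'
#' Takes absolute values and divides by the channel maximum so the peak is
#' exactly 1. An identically-zero channel is returned as zeros with a warning
#' (degenerate channel).
#'
#' @param signal Numeric series.
#' @return Series in \[0, 1\].
#' @export
rectify_and_normalize <- function(signal) {
  if (length(signal) < 1L) stop("signal must be non-empty")
  r <- abs(signal)
  m <- max(r)
  if (m == 0) {
    warning("channel is identically zero; returning zeros")
    return(r)
  }
  r / m
}

#' Condition a raw recording into normalized activation envelopes
#'
#' Per channel, applies the linear-envelope chain: DC removal, zero-phase
#' 30 Hz high-pass (motion artefact), full-wave rectification, zero-phase
#' 6 Hz low-pass, and normalization to the channel maximum. Torque passes
#' through unfiltered; for supinated recordings its sign is flipped at this
#' stage (if configured) so flexion is always positive internally.
#'
#' Small negative low-pass undershoots are clipped to zero before
#' normalization so envelopes stay in \[0, 1\].
#'
#' @param raw A `semg_recording`.
#' @param config A [processing_config()].
#' @return A `processed_recording`.
#' @export
process_recording <- function(raw, config = processing_config()) {
  stopifnot(inherits(raw, "semg_recording"))
  semg <- raw$semg
  env <- matrix(0, nrow(semg), ncol(semg),
                dimnames = list(NULL, colnames(semg)))
  for (j in seq_len(ncol(semg))) {
    x <- tryCatch({
      x <- remove_dc(semg[, j])
      x <- zero_lag_butterworth(x, config$highpass_hz, "highpass",
                                config$order, raw$sample_rate_hz,
                                config$pad_factor)
      x <- abs(x)
      x <- zero_lag_butterworth(x, config$lowpass_hz, "lowpass",
                                config$order, raw$sample_rate_hz,
                                config$pad_factor)
      rectify_and_normalize(pmax(x, 0))
    }, error = function(e) {
      stop("channel ", colnames(semg)[j], ": ", conditionMessage(e),
           call. = FALSE)
    })
    env[, j] <- x
  }
  torque <- raw$torque
  flipped <- FALSE
  if (config$flip_supinated_torque && raw$posture == "supinated") {
    torque <- -torque
    flipped <- TRUE
  }
  prov <- c("remove_dc",
            sprintf("highpass_%ghz_order%d_zero_lag",
                    config$highpass_hz, config$order),
            "rectify",
            sprintf("lowpass_%ghz_order%d_zero_lag",
                    config$lowpass_hz, config$order),
            "normalize_per_channel",
            if (flipped) "flip_supinated_torque")
  processed_recording(env, torque, raw$sample_rate_hz, prov,
                      meta = list(subject_id = raw$subject_id,
                                  session_id = raw$session_id,
                                  posture = raw$posture))
}

#' Decimate a processed recording, keeping every k-th sample
#'
#' Samples are taken at indices k, 2k, ... (1-based), identically for
#' envelopes and torque, yielding `floor(N / k)` samples; a 33,520-sample
#' recording decimated with k = 100 yields exactly 335.
#'
#' @param processed A `processed_recording`.
#' @param k Positive integer decimation step.
#' @return A decimated `processed_recording`.
#' @export
resample_every <- function(processed, k) {
  stopifnot(inherits(processed, "processed_recording"))
  k <- as.integer(k)
  n <- nrow(processed$envelopes)
  if (k < 1L) stop("k must be a positive integer")
  if (k > n) stop("k exceeds the number of samples (", n, ")")
  idx <- seq.int(k, n, by = k)
  processed_recording(processed$envelopes[idx, , drop = FALSE],
                      processed$torque[idx],
                      processed$sample_rate_hz / k,
                      c(processed$provenance, sprintf("resample_every_%d", k)),
                      processed$meta)
}
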
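# Shared fixtures: everything is generated in code at test time.

# Small cohort configuration for fast unit tests (full study scale is
# exercised in the acceptance tests).
small_config <- function(n_samples = 8000, ...) {
  cohort_config(n_samples = n_samples, ...)
}

# A processed recording built directly from envelope values in [0, 1],
# bypassing the raw-signal chain.
make_processed <- function(envelopes, torque, fs = 1000) {
  processed_recording(envelopes, torque, fs, provenance = "synthetic")
}

# Noiseless "ideal envelope" recording for a synthetic subject: the
# excitations themselves serve as envelopes and the torque is the
# ground-truth forward model (optionally with noise). This is the
# calibration recovery fixture.
ideal_recording <- function(subject, schedule_seed = 1, noise_sd = 0) {
  exc <- generate_excitation_schedule(subject$config, schedule_seed)
  tau <- synthesize_torque(exc, subject, noise_sd = noise_sd,
                           seed = schedule_seed + 1)
  make_processed(exc, tau, subject$config$sample_rate_hz)
}

# Deterministic linear regression fixture.
linear_problem <- function(n, m, beta, noise_sd = 0, seed = 1) {
  X <- with_test_seed(seed, matrix(runif(n * m), n, m))
  y <- as.numeric(X %*% beta)
  if (noise_sd > 0)
    y <- y + with_test_seed(seed + 1, rnorm(n, 0, noise_sd))
  regression_problem(X, y)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
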
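test_that("remove_dc subtracts the mean exactly", {
  expect_equal(remove_dc(rep(0.5, 100)), rep(0, 100))
  expect_equal(remove_dc(c(1, 2, 3)), c(-1, 0, 1))
  x <- with_test_seed(1, rnorm(500))
  x <- x - mean(x)
  expect_equal(remove_dc(x), x, tolerance = 1e-12)
  expect_error(remove_dc(numeric(0)), "non-empty")
})

test_that("zero-lag Butterworth attenuates out-of-band content and is linear", {
  expect_equal(zero_lag_butterworth(numeric(2000), 30, "highpass"),
               numeric(2000))
  # 1 Hz sinusoid through the 30 Hz high-pass: the squared analytic
  # Butterworth magnitude at 1 Hz is (1/30)^8 for the bidirectional 4th
  # order design, so the residual must be far below 1% of the input
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)
  y <- zero_lag_butterworth(x, 30, "highpass", 4, fs)
  expect_lt(max(abs(y)), 0.01)
})

test_that("forward-backward filtering has zero phase lag", {
  pulse <- c(rep(0, 400), seq(0, 1, length.out = 101),
             seq(1, 0, length.out = 101)[-1], rep(0, 400))
  out <- zero_lag_butterworth(pulse, 6, "lowpass", 4, 1000)
  cc <- stats::ccf(pulse, out, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # filtering the reversed input and reversing equals filtering the input:
  # exact in the interior, approximate within the padded edge regions
  x <- with_test_seed(2, rnorm(3000))
  a <- zero_lag_butterworth(x, 6, "lowpass", 4, 1000)
  b <- rev(zero_lag_butterworth(rev(x), 6, "lowpass", 4, 1000))
  expect_lt(max(abs(a - b)), 0.01)
  interior <- 1000:2000   # edge transients decay within ~1 s at 6 Hz
  expect_equal(a[interior], b[interior], tolerance = 1e-7)
})

test_that("invalid filter parameters are rejected", {
  expect_error(zero_lag_butterworth(rnorm(100), 500, "lowpass",
                                    sample_rate_hz = 1000), "Nyquist")
  expect_error(zero_lag_butterworth(rnorm(100), 600, "lowpass",
                                    sample_rate_hz = 1000), "Nyquist")
  expect_error(zero_lag_butterworth(rnorm(10), 30, "highpass", 4, 1000),
               "short")
})

test_that("rectify_and_normalize maps onto [0,1] with unit peak", {
  expect_equal(rectify_and_normalize(c(-1, 0.5, 0.25)), c(1, 0.5, 0.25))
  x <- with_test_seed(3, rnorm(200))
  r <- rectify_and_normalize(x)
  expect_equal(max(r), 1)
  expect_true(all(r >= 0 & r <= 1))
  expect_warning(z <- rectify_and_normalize(numeric(50)), "zero")
  expect_equal(z, numeric(50))
})

test_that("processing chain removes DC and sub-6-Hz drift power", {
  fs <- 1000
  n <- 10000
  t <- seq_len(n) / fs
  carrier <- with_test_seed(4, rnorm(n))
  bt <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  carrier <- signal::filter(bt, carrier)
  env0 <- 0.5 + 0.5 * sin(2 * pi * 0.2 * t)
  raw <- 0.001 * env0 * carrier + 0.3 + 0.05 * sin(2 * pi * 2 * t)
  semg <- matrix(rep(raw, 8), ncol = 8)
  rec <- recording(semg, numeric(n), fs)
  # band-power oracle on the pre-rectification high-passed signal: power
  # below 6 Hz must drop by > 99% relative to the raw channel
  band_power_below <- function(x, f_hi) {
    sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
    sum(sp$spec[sp$freq * fs < f_hi])
  }
  hp <- zero_lag_butterworth(remove_dc(raw), 30, "highpass", 4, fs)
  expect_lt(band_power_below(hp, 6) / band_power_below(raw, 6), 0.01)
  pr <- process_recording(rec)
  expect_true(all(pr$envelopes >= 0 & pr$envelopes <= 1))
})

test_that("envelope tracks a known amplitude-modulation profile", {
  fs <- 1000
  n <- 20000
  t <- seq_len(n) / fs
  profile <- pmax(sin(2 * pi * 0.15 * t), 0)
  carrier <- with_test_seed(5, rnorm(n))
  bt <- signal::butter(4, c(60, 140) / (fs / 2), type = "pass")
  carrier <- signal::filter(bt, carrier)
  raw <- profile * carrier
  rec <- recording(matrix(rep(raw, 8), ncol = 8), numeric(n), fs)
  pr <- process_recording(rec)
  expect_gt(cor(pr$envelopes[, 1], profile), 0.95)
  expect_equal(max(pr$envelopes[, 1]), 1)
})

test_that("zero recordings give zero envelopes with warnings", {
  rec <- recording(matrix(0, 500, 8), numeric(500))
  warns <- capture_warnings(pr <- process_recording(rec))
  expect_length(warns, 8)           # one degenerate-channel warning each
  expect_match(warns, "zero", all = TRUE)
  expect_true(all(pr$envelopes == 0))
})

test_that("processing is deterministic and leaves torque unfiltered", {
  cfg <- small_config(4000)
  sub <- synthetic_subject(cfg, seed = 11)
  exc <- generate_excitation_schedule(cfg, seed = 3)
  tau <- synthesize_torque(exc, sub, noise_sd = 0.05, seed = 9)
  rec <- recording(synthesize_raw_semg(exc, sub, seed = 4), tau)
  a <- process_recording(rec)
  b <- process_recording(rec)
  expect_identical(a$envelopes, b$envelopes)
  expect_identical(a$torque, tau)
})

test_that("supinated torque sign is harmonized at processing time", {
  n <- 2000
  semg <- matrix(with_test_seed(6, rnorm(n * 8, sd = 1e-3)), ncol = 8)
  tau <- sin(seq(0, 4 * pi, length.out = n))
  sup <- recording(semg, tau, posture = "supinated")
  pr <- process_recording(sup)
  expect_equal(pr$torque, -tau)
  pr2 <- process_recording(sup, processing_config(flip_supinated_torque = FALSE))
  expect_equal(pr2$torque, tau)
})

test_that("resample_every decimates on the k-th sample grid", {
  env <- matrix(with_test_seed(7, runif(33520 * 2)), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  pr <- make_processed(env, seq_len(33520))
  dec <- resample_every(pr, 100)
  expect_identical(nrow(dec$envelopes), 335L)
  expect_equal(dec$torque[1], 100)          # indices k, 2k, ...
  expect_equal(resample_every(pr, 1)$torque, pr$torque)
  one <- resample_every(make_processed(env[1:100, ], 1:100), 100)
  expect_identical(length(one$torque), 1L)
  expect_error(resample_every(make_processed(env[1:50, ], 1:50), 51),
               "exceeds")
  # resampling then identity-resampling equals resampling once
  expect_equal(resample_every(dec, 1)$envelopes, dec$envelopes)
})

test_that("configuration files round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("highpass_hz: 25", "lowpass_hz: 5", "resample_k: 50"), path)
  cfg <- read_processing_config(path)
  expect_equal(cfg$highpass_hz, 25)
  expect_equal(cfg$lowpass_hz, 5)
  expect_identical(cfg$resample_k, 50L)
  expect_identical(cfg$order, 4L)           # defaults fill the gaps
  path2 <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "population: 20", "generations: 15",
               "polish: false"), path2)
  ga <- read_calibration_config(path2)
  expect_identical(ga$seed, 9L)
  expect_identical(ga$population, 20L)
  expect_identical(ga$generations, 15L)
  expect_false(ga$polish)
})
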
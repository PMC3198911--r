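test_that("the excitation schedule follows the 14-action protocol", {
  cfg <- small_config()
  exc <- generate_excitation_schedule(cfg, seed = 3)
  seg <- attr(exc, "segments")
  expect_identical(nrow(seg), 14L)
  expect_identical(sum(seg$level == 1), 2L)     # one MVC per direction
  expect_identical(sum(seg$level == 0.5), 6L)
  expect_identical(sum(seg$level == 0.25), 6L)
  expect_true(all(exc >= 0 & exc <= 1))
  expect_identical(nrow(exc), cfg$n_samples)
  # 25%-MVC peaks are about half the 50%-MVC peaks per muscle
  peak_at <- function(lv) {
    rows <- unlist(mapply(seq, seg$start[seg$level == lv],
                          seg$end[seg$level == lv]))
    apply(exc[rows, , drop = FALSE], 2, max)
  }
  ratio <- peak_at(0.25) / peak_at(0.5)
  expect_true(all(abs(ratio - 0.5) < 0.2))
  expect_identical(exc, generate_excitation_schedule(cfg, seed = 3))
  expect_false(identical(exc, generate_excitation_schedule(cfg, seed = 4)))
})

test_that("ground-truth torque has the right signs and determinism", {
  cfg <- small_config()
  sub <- synthetic_subject(cfg, seed = 6)
  expect_equal(synthesize_torque(matrix(0, 100, 8), sub), numeric(100))
  exc <- generate_excitation_schedule(cfg, seed = 2)
  flex_only <- exc
  flex_only[, 1:4] <- 0   # silence extensors
  tau <- synthesize_torque(flex_only, sub)
  expect_gte(min(tau), -1e-9)
  t1 <- synthesize_torque(exc, sub, noise_sd = 0.1, seed = 5)
  t2 <- synthesize_torque(exc, sub, noise_sd = 0.1, seed = 5)
  expect_identical(t1, t2)
})

test_that("the carrier concentrates its power in the 20-450 Hz band", {
  x <- with_test_seed(4, semgtorque:::emg_carrier(20000, 1000, c(20, 450)))
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
  f <- sp$freq * 1000
  in_band <- sum(sp$spec[f >= 20 & f <= 450])
  expect_gt(in_band / sum(sp$spec), 0.95)
})

test_that("raw SEMG is linear in the channel gain", {
  cfg <- small_config(3000)
  sub <- synthetic_subject(cfg, seed = 9)
  sub$noise$dc_offset_V[] <- 0
  sub$noise$drift_amp_V[] <- 0
  sub$noise$measurement_sd_V <- 0
  exc <- generate_excitation_schedule(cfg, seed = 1)
  s1 <- synthesize_raw_semg(exc, sub, seed = 7)
  sub2 <- sub
  sub2$channel_gains <- 2 * sub$channel_gains
  s2 <- synthesize_raw_semg(exc, sub2, seed = 7)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  # zero excitations leave only the noise model
  sub$noise$measurement_sd_V <- 1e-5
  s0 <- synthesize_raw_semg(matrix(0, 3000, 8), sub, seed = 7)
  expect_lt(max(abs(s0)), 1e-3)
})

test_that("processed envelopes track the mixed excitations", {
  cfg <- small_config()
  sub <- synthetic_subject(cfg, seed = 13)
  exc <- generate_excitation_schedule(cfg, seed = 2)
  rec <- recording(synthesize_raw_semg(exc, sub, seed = 3),
                   synthesize_torque(exc, sub))
  pr <- process_recording(rec)
  mixed <- exc %*% t(sub$crosstalk)
  cors <- sapply(1:8, function(j) cor(pr$envelopes[, j], mixed[, j]))
  expect_true(all(cors > 0.9))
})

test_that("apply_drift is identity-stable and validates its input", {
  cfg <- small_config(4000)
  sub <- synthetic_subject(cfg, seed = 17)
  rec <- semgtorque:::generate_session(sub, 1, 2)
  same <- apply_drift(rec, drift_spec())
  expect_equal(same$semg, rec$semg, tolerance = 1e-12)
  expect_equal(same$torque, rec$torque, tolerance = 1e-12)
  plain <- recording(rec$semg, rec$torque)
  expect_error(apply_drift(plain, drift_spec()), "provenance")
  bad <- drift_spec(gain_drift = rep(-1, 8))
  expect_error(apply_drift(rec, bad), "negative")
})

test_that("a posture remap flips the recorded torque sign before load-time
           harmonization", {
  cfg <- small_config(4000)
  sub <- synthetic_subject(cfg, seed = 19)
  rec <- semgtorque:::generate_session(sub, 1, 2)
  remap <- semgtorque:::posture_remap_matrix(sub$crosstalk, 0.5)
  sup <- apply_drift(rec, drift_spec(posture_remap = remap,
                                     flip_torque = TRUE),
                     posture = "supinated")
  syn <- attr(rec, "synthesis")
  flex <- syn$noiseless_torque > 0.5
  expect_true(all(sup$torque[flex] < 0))
  pr <- process_recording(sup)
  expect_gt(max(pr$torque[flex]), 0)  # harmonized back to flexion-positive
})

test_that("cohorts are reproducible and sized to the protocol", {
  cfg <- small_config()
  c1 <- generate_cohort(2, cfg, master_seed = 5)
  c2 <- generate_cohort(2, cfg, master_seed = 5)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$subjects[[1]]$recordings$s2$semg,
                   c2$subjects[[1]]$recordings$s2$semg)
  recs <- c1$subjects[[1]]$recordings
  expect_identical(sort(names(recs)),
                   c("s1_pronated", "s1_supinated", "s2", "s3"))
  expect_identical(nrow(recs$s1_pronated$semg), cfg$n_samples)
  expect_identical(recs$s1_supinated$posture, "supinated")
  path <- tempfile(fileext = ".json")
  write_manifest(c1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$master_seed, 5L)
  expect_identical(nrow(back$subjects), 2L)
})

test_that("generator and forward model agree on noiseless data", {
  cfg <- small_config()
  sub <- synthetic_subject(cfg, seed = 23)
  exc <- generate_excitation_schedule(cfg, seed = 4)
  tau <- synthesize_torque(exc, sub)     # noiseless
  pr <- make_processed(exc, tau, cfg$sample_rate_hz)
  tau_fwd <- forward_pbm(pr, sub$ground_truth)
  expect_lt(nrmse(tau_fwd, tau), 0.02)
})

test_that("recordings round-trip through the CSV + JSON interchange format", {
  cfg <- small_config(1000)
  sub <- synthetic_subject(cfg, seed = 29)
  exc <- generate_excitation_schedule(cfg, seed = 1)
  rec <- recording(synthesize_raw_semg(exc, sub, seed = 2),
                   synthesize_torque(exc, sub),
                   session_id = "s2", posture = "supinated",
                   subject_id = "sub99")
  csv <- tempfile(fileext = ".csv")
  write_recording(rec, csv)
  back <- read_recording(csv)
  expect_equal(back$semg, rec$semg, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$torque, rec$torque, tolerance = 1e-9)
  expect_identical(back$session_id, "s2")
  expect_identical(back$posture, "supinated")
  expect_identical(back$channel_names, rec$channel_names)
})
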
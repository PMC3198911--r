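# Fast plan for harness plumbing tests: linear models only, light GA.
fast_plan <- function(models = c("ols", "lwpr"), seed = 1) {
  experiment_plan(models = models, seed = seed,
                  ga = ga_config(population = 16, generations = 10,
                                 stagnation = 5, polish_maxit = 15))
}

test_that("a single-subject channel experiment emits one row per channel set", {
  co <- generate_cohort(1, small_config(), master_seed = 3)
  res <- channel_subset_experiment(co, fast_plan("ols"))
  expect_identical(nrow(res$results), 3L)
  expect_setequal(res$results$condition, c("8ch", "5ch", "2ch"))
  expect_identical(res$results$k, c(8L, 5L, 2L))
  expect_true(res$results$best_pair[res$results$condition == "2ch"] %in%
                names(primary_pairs()))
  expect_true(all(c("nrmse", "r2", "ra2") %in% names(res$results)))
})

test_that("experiments are reproducible from their seeds", {
  co <- generate_cohort(1, small_config(), master_seed = 4)
  plan <- fast_plan(c("ols", "lwpr"), seed = 11)
  a <- training_fraction_experiment(co, plan, fractions = c(0.5, 0.75))
  b <- training_fraction_experiment(co, plan, fractions = c(0.5, 0.75))
  expect_identical(a$results, b$results)
})

test_that("an empty model list yields an empty result without error", {
  co <- generate_cohort(1, small_config(), master_seed = 5)
  plan <- fast_plan("ols")
  plan$models <- character(0)
  res <- cross_session_experiment(co, plan)
  expect_identical(nrow(res$summary), 0L)
})

test_that("invalid train fractions and missing recordings are rejected", {
  expect_error(experiment_plan(train_fraction = 1), "0, 1")
  co <- generate_cohort(1, small_config(), master_seed = 6)
  co$subjects[[1]]$recordings$s2 <- NULL
  expect_error(cross_session_experiment(co, fast_plan("ols")), "s2")
  pr <- process_recording(co$subjects[[1]]$recordings$s1_pronated)
  expect_error(semgtorque:::split_indices(pr, 0.001, 100), "empty")
})

test_that("a fresh same-parameter session costs little accuracy while
           session drift degrades transfer monotonically", {
  cfg <- cohort_config()           # study-scale recording
  sub <- synthetic_subject(cfg, seed = 31)
  s1 <- semgtorque:::generate_session(sub, 1, 2)
  drifts <- with_test_seed(99, {
    g <- runif(8, 0.7, 1.3)
    p2 <- runif(8, 0.7, 1.35)
    p3 <- runif(8, 0.6, 1.5)
    sh <- matrix(runif(64, 0, 0.15), 8, 8)
    diag(sh) <- 0
    list(g = g, p2 = p2, p3 = p3, shift = sh)
  })
  control <- semgtorque:::generate_session(sub, 10, 11)  # fresh, no drift
  hour <- semgtorque:::generate_session(
    sub, 10, 11, drift_spec(gain_drift = drifts$g,
                            amplitude_exponent = drifts$p2))
  day <- semgtorque:::generate_session(
    sub, 10, 11, drift_spec(gain_drift = drifts$g,
                            amplitude_exponent = drifts$p3,
                            electrode_shift = drifts$shift))
  pr1 <- process_recording(s1)
  sp <- semgtorque:::split_indices(pr1, 0.75, 100, "contiguous")
  m <- fit_torque_model("ols", pr1, idx = sp$train)
  base <- evaluate_model(m, pr1, range_from = pr1, idx = sp$test)$ra2
  ra2_on <- function(rec) evaluate_model(m, process_recording(rec))$ra2
  ctrl <- ra2_on(control)
  # stationarity control: a fresh protocol run with identical parameters
  # costs almost nothing
  expect_lt(abs(base - ctrl), 0.05)
  # drift degrades transfer, and more perturbation degrades it more
  expect_gt(ctrl, ra2_on(hour))
  expect_gt(ra2_on(hour), ra2_on(day))
  expect_gt(ctrl - ra2_on(day), 0.02)
})

test_that("an identity posture perturbation leaves accuracy unchanged", {
  cfg <- cohort_config()
  sub <- synthetic_subject(cfg, seed = 37)
  s1 <- semgtorque:::generate_session(sub, 1, 2)
  identity_remap <- apply_drift(s1, drift_spec())   # no perturbation
  pr1 <- process_recording(s1)
  sp <- semgtorque:::split_indices(pr1, 0.75, 100, "random", seed = 4)
  m <- fit_torque_model("ols", pr1, idx = sp$train)
  base <- evaluate_model(m, pr1, range_from = pr1, idx = sp$test)
  ctrl <- evaluate_model(m, process_recording(identity_remap),
                         range_from = pr1, idx = sp$test)
  fold <- (ctrl$nrmse - base$nrmse) / base$nrmse
  expect_lt(abs(fold), 0.2)
})

test_that("train and test samples never overlap under either split mode", {
  pr <- make_processed(matrix(runif(5000 * 2), ncol = 2,
                              dimnames = list(NULL, c("a", "b"))),
                       runif(5000))
  for (mode in c("contiguous", "random", "blocks")) {
    sp <- semgtorque:::split_indices(pr, 0.75, 100, mode, seed = 2)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_equal(sort(c(sp$train, sp$test)), seq(100, 5000, 100))
  }
})

test_that("resampled and full-rate training give statistically
           indistinguishable accuracy", {
  co <- generate_cohort(3, small_config(), master_seed = 9)
  vals <- sapply(c(100L, 1L), function(k) {
    sapply(co$subjects, function(s) {
      pr <- process_recording(s$recordings$s1_pronated)
      sp <- semgtorque:::split_indices(pr, 0.75, 100)
      m <- fit_torque_model("ols", pr, resample_k = k,
                            idx = if (k == 1L)
                              seq_len(max(sp$train)) else sp$train)
      evaluate_model(m, pr, range_from = pr, idx = sp$test)$nrmse
    })
  })
  r <- one_way_anova(list(vals[, 1], vals[, 2]))
  expect_true(is.finite(r$F))
  expect_gt(r$p, 0.05)
})

test_that("cohort summaries carry means and SDs across subjects and ANOVA
           across models runs on them", {
  co <- generate_cohort(2, small_config(), master_seed = 10)
  res <- posture_experiment(co, fast_plan(c("ols", "lwpr")))
  s <- res$summary
  expect_true(all(c("nrmse_mean_pct", "nrmse_sd_pct", "ra2_mean",
                    "ra2_sd") %in% names(s)))
  expect_true(all(s$n_subjects == 2))
  expect_true(all(s$nrmse_sd_pct >= 0))
  by_model <- split(res$results$ra2[res$results$condition == "supinated"],
                    res$results$model[res$results$condition == "supinated"])
  r <- one_way_anova(by_model)
  expect_true(is.finite(r$F) && is.finite(r$p))
  ch <- condition_changes(res, "baseline", "supinated", "fold")
  expect_true(all(is.finite(ch$nrmse_change)))
  paths <- write_cohort_result(res, tempfile(fileext = ".csv"),
                               tempfile(fileext = ".json"))
  expect_true(all(file.exists(paths)))
})
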
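#' Experiment plan
#'
#' Shared settings for the four cohort studies: which models to run, the
#' train fraction for same-session evaluation, decimation step, fitter
#' seeds, and the GA budget used for per-condition physiological-model
#' calibration (smaller than the standalone default because each cohort run
#' performs many calibrations; the budget is configurable).
#'
#' @param models Subset of `c("pbm","ols","rls","svr","ann","lwpr")`.
#' @param train_fraction Training fraction in (0, 1) for the same-session
#'   baseline split.
#' @param split `"random"` (seeded random sample assignment, the default:
#'   every test condition is then evaluated on a window representative of
#'   the whole protocol), `"blocks"` (random contiguous blocks) or
#'   `"contiguous"` (first block trains, preserving time-series
#'   structure).
#' @param resample_k Decimation step.
#' @param seed Plan seed; per-(subject, model, condition) seeds derive from
#'   it.
#' @param ga [ga_config()] used for `"pbm"` fits inside experiments.
#' @param lambda `"rls"` regularization parameter.
#' @param est_configs Named list of [estimator_config()] objects overriding
#'   the ML-model settings inside experiments. The default uses a reduced
#'   SVR grid (cohort runs perform hundreds of grid searches; the standalone
#'   [estimator_config()] default keeps the full grid).
#' @param best_pair_metric Metric used to pick the best two-channel pair:
#'   `"ra2"` (default) or `"nrmse"`.
#' @return A list of class `experiment_plan`.
#' @export
experiment_plan <- function(models = c("pbm", "ols", "rls", "svr", "ann",
                                       "lwpr"),
                            train_fraction = 0.75,
                            split = c("random", "blocks", "contiguous"),
                            resample_k = 100,
                            seed = 1,
                            ga = ga_config(population = 30, generations = 25,
                                           stagnation = 8,
                                           polish_maxit = 30),
                            lambda = 0.01,
                            est_configs = list(
                              svr = estimator_config(
                                "svr",
                                svr_grid = list(C = c(1, 10, 100),
                                                gamma = c(0.1, 1),
                                                epsilon = c(0.01, 0.1)))),
                            best_pair_metric = c("ra2", "nrmse")) {
  models <- match.arg(models, c("pbm", "ols", "rls", "svr", "ann", "lwpr"),
                      several.ok = TRUE)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie in (0, 1)")
  structure(list(models = models, train_fraction = train_fraction,
                 split = match.arg(split),
                 resample_k = as.integer(resample_k),
                 seed = as.integer(seed), ga = ga, lambda = lambda,
                 est_configs = est_configs,
                 best_pair_metric = match.arg(best_pair_metric)),
            class = "experiment_plan")
}

#' Primary wrist muscle channels and candidate two-channel pairs
#'
#' The five primary wrist movers among the monitored muscles, and the six
#' flexor/extensor pairs formed from them (one primary flexor x one primary
#' extensor).
#'
#' @return `primary_channels()`: character vector of 5 channels.
#'   `primary_pairs()`: list of 6 two-channel character vectors.
#' @export
primary_channels <- function() c("ECRL", "ECU", "ECRB", "FCR", "FCU")

#' @rdname primary_channels
#' @export
primary_pairs <- function() {
  flexors <- c("FCR", "FCU")
  extensors <- c("ECRL", "ECRB", "ECU")
  out <- list()
  for (f in flexors) for (e in extensors) out[[paste(f, e, sep = "-")]] <- c(f, e)
  out
}

# Split the decimated sample grid of a full-rate recording into train and
# test indices (full-rate coordinates). Contiguous: first fraction trains.
# Random: seeded random sample assignment. Blocks: seeded random assignment
# of contiguous blocks (default 12 decimated samples, about half an action
# segment), preserving local time structure so a small training fraction
# genuinely misses parts of the protocol. Train and test never overlap.
split_indices <- function(pr, fraction, k, mode = "contiguous", seed = 1,
                          block_len = 12L) {
  n <- nrow(pr$envelopes)
  grid <- seq.int(k, n, by = k)
  n_train <- floor(fraction * length(grid))
  if (n_train < 1 || n_train >= length(grid))
    stop("train fraction leaves an empty train or test set")
  if (mode == "random") {
    sel <- with_seed(seed, sample(length(grid), n_train))
    train <- sort(grid[sel])
  } else if (mode == "blocks") {
    block <- ceiling(seq_along(grid) / block_len)
    nb <- max(block)
    ord <- with_seed(seed, sample(nb))
    csize <- cumsum(tabulate(block)[ord])
    n_blocks <- which.min(abs(csize - n_train))
    train <- sort(grid[block %in% ord[seq_len(n_blocks)]])
  } else {
    train <- grid[seq_len(n_train)]
  }
  list(train = train, test = setdiff(grid, train))
}

fit_seed <- function(plan, subject_i, model, tag) {
  derive_seed(plan$seed,
              subject_i * 131L + match(model, c("pbm", "ols", "rls", "svr",
                                                "ann", "lwpr")) * 17L +
                sum(utf8ToInt(tag)))
}

# Fit one model on a channel subset and evaluate it on one or more test
# conditions. Each test is list(pr, idx = NULL, range = NULL); `range` (a
# processed_recording) supplies the session-level torque extrema for NRMSE
# when the test samples cover only a narrow window. One row per condition.
fit_and_eval <- function(model, train_pr, train_idx, tests, channels, plan,
                         subject_i, tag, tab, sigma_pcsa = NULL,
                         cache = NULL) {
  seed <- fit_seed(plan, subject_i, model, tag)
  key <- paste(subject_i, model, paste(channels, collapse = ","),
               length(train_idx), sum(train_idx), seed, sep = "|")
  tm <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
  else fit_torque_model(model, subset_channels(train_pr, channels),
                        resample_k = plan$resample_k, seed = seed,
                        tab = tab, sigma_pcsa = sigma_pcsa,
                        ga = plan$ga, lambda = plan$lambda,
                        est_config = plan$est_configs[[model]],
                        idx = train_idx)
  if (!is.null(cache)) cache[[key]] <- tm
  rows <- lapply(names(tests), function(cond) {
    te <- tests[[cond]]
    rf <- if (!is.null(te$range)) te$range else te$pr
    ev <- evaluate_model(tm, te$pr, range_from = rf, idx = te$idx)
    data.frame(model = model, condition = cond, nrmse = ev$nrmse,
               r2 = ev$r2, ra2 = ev$ra2, n = ev$n, k = ev$k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

result_frame <- function(rows, subject_id) {
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$subject_id <- subject_id
  out[c("subject_id", setdiff(names(out), "subject_id"))]
}

#' Channel-subset experiment (8 vs 5 vs best-of-6 two-channel)
#'
#' Per subject, trains every model on the session-1 pronated recording using
#' all eight channels, the five primary channels, and each of the six
#' flexor/extensor pairs (75/25 split), picking each subject's best pair by
#' held-out performance. The physiological model uses the full PCSA table
#' for eight channels and the role-wise PCSA redistribution for the reduced
#' sets.
#'
#' @param cohort A `synthetic_cohort` (or any list of subjects with
#'   `recordings$s1_pronated`).
#' @param plan An [experiment_plan()].
#' @param proc_config A [processing_config()].
#' @param cache Optional environment reusing fitted models across
#'   experiments when data, channels and seed coincide.
#' @return A `cohort_result` list: `results` (tidy per-subject data.frame
#'   with conditions `8ch`, `5ch`, `2ch` and the chosen `best_pair`),
#'   `summary` (means/SDs).
#' @export
channel_subset_experiment <- function(cohort, plan = experiment_plan(),
                                      proc_config = processing_config(),
                                      cache = NULL) {
  tab <- cohort$config$tab
  rows <- list()
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    pr <- process_recording(sub$recordings$s1_pronated, proc_config)
    sp <- split_indices(pr, plan$train_fraction, plan$resample_k,
                        plan$split, derive_seed(plan$seed, i))
    subject_rows <- list()
    for (model in plan$models) {
      heldout <- function(cond) {
        out <- list(list(pr = pr, idx = sp$test, range = pr))
        names(out) <- cond
        out
      }
      r8 <- fit_and_eval(model, pr, sp$train, heldout("8ch"),
                         semg_channels, plan, i, "base75", tab,
                         cache = cache)
      ch5 <- primary_channels()
      r5 <- fit_and_eval(model, pr, sp$train, heldout("5ch"), ch5, plan,
                         i, "5ch", tab,
                         sigma_pcsa = redistribute_sigma_pcsa(tab, ch5),
                         cache = cache)
      pair_rows <- lapply(names(primary_pairs()), function(pn) {
        chp <- primary_pairs()[[pn]]
        r <- fit_and_eval(model, pr, sp$train, heldout("2ch"), chp, plan,
                          i, pn, tab,
                          sigma_pcsa = redistribute_sigma_pcsa(tab, chp),
                          cache = cache)
        r$best_pair <- pn
        r
      })
      pairs <- do.call(rbind, pair_rows)
      best <- if (plan$best_pair_metric == "ra2")
        pairs[which.max(pairs$ra2), ] else pairs[which.min(pairs$nrmse), ]
      r8$best_pair <- NA_character_
      r5$best_pair <- NA_character_
      subject_rows[[model]] <- rbind(r8, r5, best)
    }
    rows[[i]] <- result_frame(subject_rows, sub$subject$subject_id)
  }
  cohort_result(do.call(rbind, rows), "channel_subset")
}

#' Training-fraction experiment (25% vs 90%)
#'
#' Splits at 25%/75% and 90%/10% using all eight channels and reports
#' per-model metrics for the two cases. Defaults to seeded random sample
#' splits: the comparison isolates the effect of training-set size, which a
#' final-block split would confound with temporal extrapolation onto a
#' single low-variance action.
#'
#' @inheritParams channel_subset_experiment
#' @param fractions Training fractions (default `c(0.25, 0.90)`).
#' @param split Split mode for this experiment. Defaults to `"blocks"`
#'   (random contiguous blocks): a small training fraction then genuinely
#'   misses parts of the protocol, as it would with sequentially collected
#'   data, while test windows remain representative of the whole session.
#' @return A `cohort_result` with conditions `train25` / `train90` (named
#'   from the fractions).
#' @export
training_fraction_experiment <- function(cohort, plan = experiment_plan(),
                                         proc_config = processing_config(),
                                         fractions = c(0.25, 0.90),
                                         split = "blocks") {
  tab <- cohort$config$tab
  rows <- list()
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    pr <- process_recording(sub$recordings$s1_pronated, proc_config)
    subject_rows <- list()
    for (model in plan$models) {
      frac_rows <- lapply(fractions, function(f) {
        sp <- split_indices(pr, f, plan$resample_k, split,
                            derive_seed(plan$seed, i))
        cond <- sprintf("train%d", round(100 * f))
        tests <- list(list(pr = pr, idx = sp$test, range = pr))
        names(tests) <- cond
        fit_and_eval(model, pr, sp$train, tests, semg_channels, plan, i,
                     cond, tab)
      })
      subject_rows[[model]] <- do.call(rbind, frac_rows)
    }
    rows[[i]] <- result_frame(subject_rows, sub$subject$subject_id)
  }
  cohort_result(do.call(rbind, rows), "training_fraction")
}

#' Cross-session experiment (train session 1, test sessions 1/2/3)
#'
#' Models are fitted on the session-1 pronated training split and evaluated
#' on the session-1 held-out samples, the full session-2 recording (one
#' hour, electrodes attached: amplitude drift) and the full session-3
#' recording (24 hours, new electrodes: drift + cross-talk shift). Each
#' test recording is processed — and therefore normalized — on its own.
#'
#' @inheritParams channel_subset_experiment
#' @return A `cohort_result` with conditions `s1`, `s2`, `s3`.
#' @export
cross_session_experiment <- function(cohort, plan = experiment_plan(),
                                     proc_config = processing_config(),
                                     cache = NULL) {
  tab <- cohort$config$tab
  rows <- list()
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    recs <- sub$recordings
    if (is.null(recs$s2) || is.null(recs$s3))
      stop("cohort lacks sessions s2/s3")
    pr1 <- process_recording(recs$s1_pronated, proc_config)
    sp <- split_indices(pr1, plan$train_fraction, plan$resample_k,
                        plan$split, derive_seed(plan$seed, i))
    tests <- list(s1 = list(pr = pr1, idx = sp$test, range = pr1),
                  s2 = list(pr = process_recording(recs$s2, proc_config)),
                  s3 = list(pr = process_recording(recs$s3, proc_config)))
    subject_rows <- list()
    for (model in plan$models)
      subject_rows[[model]] <- fit_and_eval(model, pr1, sp$train, tests,
                                            semg_channels, plan, i,
                                            "base75", tab, cache = cache)
    rows[[i]] <- result_frame(subject_rows, sub$subject$subject_id)
  }
  cohort_result(do.call(rbind, rows), "cross_session")
}

#' Arm-posture experiment (train pronated, test supinated)
#'
#' Models fitted on the session-1 pronated training split are evaluated on
#' the held-out pronated samples (baseline) and on the same-session
#' supinated recording (torque sign harmonized at processing time).
#'
#' @inheritParams channel_subset_experiment
#' @return A `cohort_result` with conditions `baseline`, `supinated`.
#' @export
posture_experiment <- function(cohort, plan = experiment_plan(),
                               proc_config = processing_config(),
                               cache = NULL) {
  tab <- cohort$config$tab
  rows <- list()
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    recs <- sub$recordings
    if (is.null(recs$s1_supinated)) stop("cohort lacks supinated recordings")
    pr1 <- process_recording(recs$s1_pronated, proc_config)
    sp <- split_indices(pr1, plan$train_fraction, plan$resample_k,
                        plan$split, derive_seed(plan$seed, i))
    tests <- list(baseline = list(pr = pr1, idx = sp$test, range = pr1),
                  supinated = list(pr = process_recording(recs$s1_supinated,
                                                          proc_config)))
    subject_rows <- list()
    for (model in plan$models)
      subject_rows[[model]] <- fit_and_eval(model, pr1, sp$train, tests,
                                            semg_channels, plan, i,
                                            "base75", tab, cache = cache)
    rows[[i]] <- result_frame(subject_rows, sub$subject$subject_id)
  }
  cohort_result(do.call(rbind, rows), "posture")
}

cohort_result <- function(results, experiment) {
  structure(list(experiment = experiment, results = results,
                 summary = summarize_cohort(results)),
            class = "cohort_result")
}

#' Cohort summary: unweighted means and SDs across subjects
#'
#' Per (model, condition): mean and SD of NRMSE (as percent) and adjusted
#' R², matching the grain of the study's summary tables.
#'
#' @param results Tidy per-subject results data.frame.
#' @return Data.frame with `model`, `condition`, `nrmse_mean_pct`,
#'   `nrmse_sd_pct`, `ra2_mean`, `ra2_sd`, `n_subjects`.
#' @export
summarize_cohort <- function(results) {
  if (is.null(results) || !nrow(results))
    return(data.frame(model = character(), condition = character(),
                      nrmse_mean_pct = numeric(), nrmse_sd_pct = numeric(),
                      ra2_mean = numeric(), ra2_sd = numeric(),
                      n_subjects = integer()))
  agg <- split(results, list(results$model, results$condition), drop = TRUE)
  out <- do.call(rbind, lapply(agg, function(g) {
    data.frame(model = g$model[1], condition = g$condition[1],
               nrmse_mean_pct = mean(g$nrmse) * 100,
               nrmse_sd_pct = sd(g$nrmse) * 100,
               ra2_mean = mean(g$ra2), ra2_sd = sd(g$ra2),
               n_subjects = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$model, out$condition), ]
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result: %s>\n", x$experiment))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Relative-change summary between two conditions of a cohort result
#'
#' Applies [relative_change()] to the cohort means of each model, reporting
#' the degradation (or improvement) of NRMSE and adjusted R² from a
#' reference condition to a comparison condition.
#'
#' @param result A `cohort_result`.
#' @param from,to Condition labels.
#' @param mode `"percent"` or `"fold"`.
#' @return Data.frame with per-model `nrmse_change` and `ra2_change`.
#' @export
condition_changes <- function(result, from, to, mode = "percent") {
  s <- result$summary
  models <- unique(s$model)
  out <- lapply(models, function(m) {
    b <- s[s$model == m & s$condition == from, ]
    a <- s[s$model == m & s$condition == to, ]
    if (!nrow(b) || !nrow(a)) return(NULL)
    data.frame(model = m,
               nrmse_change = relative_change(b$nrmse_mean_pct,
                                              a$nrmse_mean_pct, mode),
               ra2_change = relative_change(b$ra2_mean, a$ra2_mean, mode),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a cohort result to tidy CSV and a JSON summary
#'
#' @param result A `cohort_result`.
#' @param csv_path Per-subject tidy CSV path.
#' @param json_path Summary JSON path.
#' @return Invisibly, the paths.
#' @export
write_cohort_result <- function(result, csv_path, json_path) {
  write.csv(result$results, csv_path, row.names = FALSE)
  jsonlite::write_json(list(experiment = result$experiment,
                            summary = result$summary),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' Run the full four-experiment study on a synthetic cohort
#'
#' Generates (or accepts) a cohort and runs the channel-subset,
#' training-fraction, cross-session and posture experiments.
#'
#' @param master_seed Cohort master seed.
#' @param n_subjects Cohort size (default 11).
#' @param config A [cohort_config()].
#' @param plan An [experiment_plan()].
#' @param cohort Optional pre-generated cohort (overrides generation).
#' @return Named list of four `cohort_result`s.
#' @export
run_full_study <- function(master_seed = 1, n_subjects = 11,
                           config = cohort_config(),
                           plan = experiment_plan(seed = master_seed),
                           cohort = NULL) {
  if (is.null(cohort))
    cohort <- generate_cohort(n_subjects, config, master_seed)
  # the session-1 75/25 eight-channel baseline fit is shared across the
  # channel, cross-session and posture experiments (identical data + seed)
  cache <- new.env(parent = emptyenv())
  list(channels = channel_subset_experiment(cohort, plan, cache = cache),
       fractions = training_fraction_experiment(cohort, plan),
       sessions = cross_session_experiment(cohort, plan, cache = cache),
       posture = posture_experiment(cohort, plan, cache = cache))
}
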
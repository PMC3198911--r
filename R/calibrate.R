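#' Genetic-algorithm settings for model calibration
#'
#' Real-coded GA with tournament selection, blend (BLX-alpha) crossover,
#' Gaussian mutation clipped to the box bounds, elitism, and an optional
#' bounded quasi-Newton polish of the best individual.
#'
#' @param population Population size. Default 50.
#' @param generations Maximum generations. Default 100.
#' @param elite Individuals copied unchanged each generation.
#' @param tournament_k Tournament size.
#' @param p_crossover Per-pair crossover probability.
#' @param blx_alpha Blend-crossover expansion factor.
#' @param p_mutation Per-gene mutation probability.
#' @param mutation_sd_frac Mutation SD as a fraction of each gene's range.
#' @param stagnation Stop after this many generations without improvement
#'   (Inf = run all generations).
#' @param polish Refine the GA optimum with bounded L-BFGS-B. Default TRUE.
#' @param polish_maxit Iteration cap for the polish step.
#' @param seed RNG seed; the whole run is reproducible given this seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population = 50, generations = 100, elite = 2,
                      tournament_k = 3, p_crossover = 0.9, blx_alpha = 0.5,
                      p_mutation = 0.15, mutation_sd_frac = 0.1,
                      stagnation = Inf, polish = TRUE, polish_maxit = 100,
                      seed = 1) {
  stopifnot(population >= 4, generations >= 1, elite >= 0,
            elite < population, tournament_k >= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 elite = as.integer(elite),
                 tournament_k = as.integer(tournament_k),
                 p_crossover = p_crossover, blx_alpha = blx_alpha,
                 p_mutation = p_mutation,
                 mutation_sd_frac = mutation_sd_frac,
                 stagnation = stagnation, polish = isTRUE(polish),
                 polish_maxit = as.integer(polish_maxit),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Read calibration settings from YAML
#'
#' Recognized keys match the arguments of [ga_config()] (e.g. `seed`,
#' `population`, `generations`, `polish`).
#'
#' @param path YAML file path.
#' @return A `ga_config`.
#' @export
read_calibration_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(ga_config, vals[intersect(names(vals), names(formals(ga_config)))])
}

# Box-constrained minimization of fn over [lower, upper] by a real-coded GA.
# Returns list(par, value, generations_run, evaluations, converged).
ga_optimize <- function(fn, lower, upper, config = ga_config(),
                        init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  rng <- upper - lower
  with_seed(config$seed, {
    np <- config$population
    pop <- matrix(runif(np * d), np, d)
    pop <- sweep(sweep(pop, 2, rng, "*"), 2, lower, "+")
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      k <- min(nrow(init), np)
      pop[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                     rep(lower, each = k)),
                                rep(upper, each = k))
    }
    fit <- apply(pop, 1, fn)
    evals <- np
    best_val <- min(fit)
    best_par <- pop[which.min(fit), ]
    stagnant <- 0L
    gen <- 0L
    while (gen < config$generations && stagnant < config$stagnation) {
      gen <- gen + 1L
      ord <- order(fit)
      newpop <- matrix(0, np, d)
      ne <- config$elite
      if (ne > 0) newpop[seq_len(ne), ] <- pop[ord[seq_len(ne)], , drop = FALSE]
      i <- ne
      while (i < np) {
        pick <- function() {
          cand <- sample.int(np, config$tournament_k, replace = TRUE)
          cand[which.min(fit[cand])]
        }
        p1 <- pop[pick(), ]
        p2 <- pop[pick(), ]
        if (runif(1) < config$p_crossover) {
          lo <- pmin(p1, p2)
          hi <- pmax(p1, p2)
          span <- hi - lo
          c1 <- runif(d, lo - config$blx_alpha * span,
                      hi + config$blx_alpha * span)
          c2 <- runif(d, lo - config$blx_alpha * span,
                      hi + config$blx_alpha * span)
        } else {
          c1 <- p1
          c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (i >= np) break
          mut <- runif(d) < config$p_mutation
          if (any(mut))
            child[mut] <- child[mut] +
              rnorm(sum(mut), 0, config$mutation_sd_frac * rng[mut])
          i <- i + 1L
          newpop[i, ] <- pmin(pmax(child, lower), upper)
        }
      }
      pop <- newpop
      fit <- apply(pop, 1, fn)
      evals <- evals + np
      gbest <- min(fit)
      if (gbest < best_val - abs(best_val) * 1e-10) {
        best_val <- gbest
        best_par <- pop[which.min(fit), ]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
    }
    converged <- TRUE
    if (config$polish) {
      pol <- tryCatch(
        optim(best_par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(maxit = config$polish_maxit)),
        error = function(e) NULL)
      if (!is.null(pol) && pol$value <= best_val) {
        # L-BFGS-B can land an epsilon outside the box
        best_par <- pmin(pmax(pol$par, lower), upper)
        best_val <- pol$value
        converged <- pol$convergence == 0
      }
    } else {
      converged <- stagnant < config$stagnation || gen < config$generations
    }
    list(par = best_par, value = best_val, generations_run = gen,
         evaluations = evals, converged = converged)
  })
}

# Build the parameter vector bounds for calibration from a physiological
# table subset: (A, C1, C2, d_ms, Fmax_1..M, MA_1..M), Fmax and MA each
# bounded to mean +/- 1 SD (signs preserved for MA).
pbm_bounds <- function(tab, channels) {
  rows <- tab[match(channels, tab$muscle), ]
  if (anyNA(rows$muscle)) stop("unknown channels in bounds construction")
  fmax_lo <- pmax(rows$fmax_mean_N - rows$fmax_sd_N, 1)
  fmax_hi <- rows$fmax_mean_N + rows$fmax_sd_N
  ma_lo <- rows$ma_mean_m - rows$ma_sd_m
  ma_hi <- rows$ma_mean_m + rows$ma_sd_m
  # keep the flexor/extensor sign fixed
  flex <- rows$role == "flexor"
  ma_lo[flex] <- pmax(ma_lo[flex], 1e-4)
  ma_hi[!flex] <- pmin(ma_hi[!flex], -1e-4)
  list(lower = c(-3, -0.95, -0.95, 10, fmax_lo, ma_lo),
       upper = c(0, 0.95, 0.95, 100, fmax_hi, ma_hi),
       rows = rows)
}

vector_to_pbm <- function(x, rows, sigma_pcsa) {
  m <- nrow(rows)
  act <- activation_params(A = x[1], C1 = x[2], C2 = x[3], d_ms = x[4])
  muscles <- lapply(seq_len(m), function(j) {
    muscle_physiology(rows$muscle[j], x[4 + j], x[4 + m + j],
                      rows$pcsa_cm2[j],
                      max(sigma_pcsa[j], rows$pcsa_cm2[j]), rows$role[j])
  })
  pbm_parameters(act, muscles)
}

#' Calibrate the physiological model to a recording by genetic algorithm
#'
#' Minimizes the sum of squared differences between modeled and measured
#' torque at the decimated sample indices, over the box-bounded parameter
#' vector (A, C1, C2, d, Fmax_1..M, MA_1..M). Activation parameters are
#' shared across muscles; Fmax and moment arms are bounded to mean ± 1 SD of
#' the physiological table; PCSA values are fixed (not calibrated). The
#' activation recursion runs at the full sample rate; only the decimated
#' samples enter the objective. The initial population includes the
#' mid-bounds parameter vector, and the returned objective never exceeds the
#' objective at that vector.
#'
#' @param processed A full-rate `processed_recording`. The activation
#'   recursion runs over the whole series; only the training samples enter
#'   the objective.
#' @param tab Physiological table ([muscle_table()]); rows are matched to the
#'   recording's channels.
#' @param config A [ga_config()].
#' @param resample_k Decimation step defining the training samples.
#' @param sigma_pcsa Optional per-channel SigmaPCSA overrides (reduced
#'   channel sets use [redistribute_sigma_pcsa()]).
#' @param idx Optional strictly increasing full-rate sample indices of the
#'   training samples (default: every `resample_k`-th sample).
#' @return List with `params` (a [pbm_parameters()]), `objective` (sum of
#'   squared residuals), `nrmse` (training NRMSE fraction), `converged`,
#'   `generations_run`.
#' @export
calibrate_pbm <- function(processed, tab = muscle_table(),
                          config = ga_config(), resample_k = 100,
                          sigma_pcsa = NULL, idx = NULL) {
  stopifnot(inherits(processed, "processed_recording"))
  channels <- colnames(processed$envelopes)
  if (is.null(channels)) stop("envelope columns must be named channels")
  b <- pbm_bounds(tab, channels)
  if (any(b$lower > b$upper)) stop("infeasible parameter bounds")
  if (is.null(sigma_pcsa)) sigma_pcsa <- b$rows$sigma_pcsa_cm2
  n <- nrow(processed$envelopes)
  if (n < 1) stop("training data is empty")
  if (is.null(idx)) idx <- seq.int(min(resample_k, n), n, by = resample_k)
  idx <- as.integer(idx)
  y <- processed$torque[idx]
  env <- processed$envelopes
  fs <- processed$sample_rate_hz
  m <- length(channels)
  pcsa_w <- sigma_pcsa / b$rows$pcsa_cm2
  objective <- function(x) {
    d <- as.integer(round(x[4] / 1000 * fs))
    w <- pcsa_w * x[5:(4 + m)] * x[(5 + m):(4 + 2 * m)]
    tau <- pbm_forward_core(env, idx, d,
                            1 + x[2] + x[3] + x[2] * x[3],
                            x[2] + x[3], x[2] * x[3], x[1], w)
    sum((tau - y)^2)
  }
  mid <- (b$lower + b$upper) / 2
  res <- ga_optimize(objective, b$lower, b$upper, config, init = mid)
  params <- vector_to_pbm(res$par, b$rows, sigma_pcsa)
  tau_hat <- forward_pbm(processed, params, idx = idx)
  list(params = params, objective = res$value,
       nrmse = nrmse(tau_hat, y), converged = res$converged,
       generations_run = res$generations_run)
}
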
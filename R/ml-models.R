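#' Machine-learning estimator configuration
#'
#' Settings for the three nonlinear regressors. SVR: Gaussian-kernel
#' epsilon-SVR with hyperparameters (C, gamma, epsilon) chosen by grid search
#' under 8-fold cross-validation. ANN: feed-forward network with two
#' tanh hidden layers trained by BFGS quasi-Newton with early stopping and
#' L2 regularization, best of 10 seeded restarts. LWPR variant: radial-basis
#' receptive fields with local linear models; the initial distance metric is
#' chosen by grid search under 8-fold cross-validation.
#'
#' @param kind One of `"svr"`, `"ann"`, `"lwpr"`.
#' @param svr_grid List with numeric vectors `C`, `gamma`, `epsilon`.
#' @param ann List with `hidden_sizes` (two layers), `max_epochs`,
#'   `patience` (epochs), `val_fraction`, `reg` (L2 strength), `restarts`.
#' @param lwpr List with `distance_grid` (RBF width grid, normalized input
#'   units), `n_fields` (receptive-field count), `ridge`.
#' @param folds Cross-validation folds (default 8).
#' @param seed RNG seed controlling folds, restarts and center placement.
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(kind = c("svr", "ann", "lwpr"),
                             svr_grid = list(C = c(0.1, 1, 10, 100),
                                             gamma = c(0.01, 0.1, 1, 10),
                                             epsilon = c(0.001, 0.01, 0.1)),
                             ann = list(hidden_sizes = c(10, 5),
                                        max_epochs = 400, patience = 20,
                                        val_fraction = 0.15, reg = 1e-4,
                                        restarts = 10),
                             lwpr = list(distance_grid = c(0.1, 0.25, 0.5, 1),
                                         n_fields = 20, ridge = 1e-6),
                             folds = 8, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "svr" && !all(lengths(svr_grid) > 0))
    stop("SVR hyperparameter grids must be nonempty")
  if (kind == "lwpr" && !length(lwpr$distance_grid))
    stop("distance metric grid must be nonempty")
  if (kind == "ann" && ann$restarts < 1) stop("restarts must be >= 1")
  if (folds < 2) stop("folds must be >= 2")
  structure(list(kind = kind, svr_grid = svr_grid, ann = ann, lwpr = lwpr,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "estimator_config")
}

# Deterministic seeded fold assignment; fold sizes differ by at most 1.
cv_folds <- function(n, folds, seed) {
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

## ---- two-hidden-layer tanh MLP trained by BFGS -------------------------

mlp_unpack <- function(theta, m, h1, h2) {
  i <- 0
  take <- function(k) {
    v <- theta[(i + 1):(i + k)]
    i <<- i + k
    v
  }
  list(W1 = matrix(take(m * h1), m, h1), b1 = take(h1),
       W2 = matrix(take(h1 * h2), h1, h2), b2 = take(h2),
       w3 = take(h2), b3 = take(1))
}

mlp_n_par <- function(m, h1, h2) m * h1 + h1 + h1 * h2 + h2 + h2 + 1

mlp_forward <- function(p, X) {
  Z1 <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
  Z2 <- tanh(sweep(Z1 %*% p$W2, 2, p$b2, "+"))
  list(Z1 = Z1, Z2 = Z2, yhat = as.numeric(Z2 %*% p$w3 + p$b3))
}

mlp_loss_grad <- function(theta, X, y, m, h1, h2, reg) {
  p <- mlp_unpack(theta, m, h1, h2)
  f <- mlp_forward(p, X)
  n <- length(y)
  err <- f$yhat - y
  loss <- mean(err^2) + reg * (sum(p$W1^2) + sum(p$W2^2) + sum(p$w3^2))
  d_y <- 2 * err / n
  g_w3 <- as.numeric(t(f$Z2) %*% d_y) + 2 * reg * p$w3
  g_b3 <- sum(d_y)
  d2 <- outer(d_y, p$w3) * (1 - f$Z2^2)
  g_W2 <- t(f$Z1) %*% d2 + 2 * reg * p$W2
  g_b2 <- colSums(d2)
  d1 <- (d2 %*% t(p$W2)) * (1 - f$Z1^2)
  g_W1 <- t(X) %*% d1 + 2 * reg * p$W1
  g_b1 <- colSums(d1)
  list(loss = loss,
       grad = c(as.numeric(g_W1), g_b1, as.numeric(g_W2), g_b2, g_w3, g_b3))
}

# One training run with early stopping on a held-out validation split.
mlp_train_once <- function(X, y, cfg, seed) {
  m <- ncol(X)
  h1 <- cfg$hidden_sizes[1]
  h2 <- cfg$hidden_sizes[2]
  n <- nrow(X)
  with_seed(seed, {
    n_val <- max(1L, floor(cfg$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    theta <- rnorm(mlp_n_par(m, h1, h2), 0, 0.5)
  })
  tr <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr, , drop = FALSE]
  ytr <- y[tr]
  Xv <- X[val_idx, , drop = FALSE]
  yv <- y[val_idx]
  fn <- function(th) mlp_loss_grad(th, Xtr, ytr, m, h1, h2, cfg$reg)$loss
  gr <- function(th) mlp_loss_grad(th, Xtr, ytr, m, h1, h2, cfg$reg)$grad
  chunk <- 10L
  best_val <- Inf
  best_theta <- theta
  waited <- 0L
  epochs <- 0L
  while (epochs < cfg$max_epochs) {
    res <- optim(theta, fn, gr, method = "BFGS",
                 control = list(maxit = chunk))
    theta <- res$par
    epochs <- epochs + chunk
    p <- mlp_unpack(theta, m, h1, h2)
    vloss <- mean((mlp_forward(p, Xv)$yhat - yv)^2)
    if (vloss < best_val - 1e-12) {
      best_val <- vloss
      best_theta <- theta
      waited <- 0L
    } else {
      waited <- waited + chunk
      if (waited >= cfg$patience) break
    }
    if (res$convergence == 0 && max(abs(gr(theta))) < 1e-8) break
  }
  list(theta = best_theta, val_loss = best_val)
}

fit_ann <- function(X, y, config) {
  cfg <- config$ann
  mu_y <- mean(y)
  sd_y <- sd(y)
  if (sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  runs <- lapply(seq_len(cfg$restarts), function(r)
    mlp_train_once(X, ys, cfg, derive_seed(config$seed, r)))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "val_loss"))]]
  list(theta = best$theta, m = ncol(X), h1 = cfg$hidden_sizes[1],
       h2 = cfg$hidden_sizes[2], mu_y = mu_y, sd_y = sd_y,
       val_loss = best$val_loss)
}

predict_ann <- function(model, X) {
  p <- mlp_unpack(model$theta, model$m, model$h1, model$h2)
  mlp_forward(p, X)$yhat * model$sd_y + model$mu_y
}

## ---- receptive-field weighted linear models (reduced LWPR variant) -----

fit_rf_net <- function(X, y, D, n_fields, ridge, seed) {
  n <- nrow(X)
  k <- min(n_fields, max(2L, floor(n / 5)))
  centers <- unique(X)
  if (nrow(centers) > k) {
    km <- with_seed(seed, kmeans(X, centers = k, iter.max = 30, nstart = 2))
    centers <- km$centers
  }
  m <- ncol(X)
  fields <- vector("list", nrow(centers))
  for (r in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(X, 2, centers[r, ], "-")^2)
    w <- exp(-0.5 * d2 / D^2)
    Xa <- cbind(1, X)
    XtW <- t(Xa * w)
    beta <- tryCatch(
      solve(XtW %*% Xa + diag(ridge, m + 1), XtW %*% y),
      error = function(e) matrix(0, m + 1, 1))
    fields[[r]] <- list(center = centers[r, ], beta = as.numeric(beta))
  }
  list(fields = fields, D = D, m = m)
}

predict_rf_net <- function(model, X) {
  n <- nrow(X)
  num <- numeric(n)
  den <- numeric(n)
  Xa <- cbind(1, X)
  for (f in model$fields) {
    d2 <- rowSums(sweep(X, 2, f$center, "-")^2)
    w <- exp(-0.5 * d2 / model$D^2)
    num <- num + w * as.numeric(Xa %*% f$beta)
    den <- den + w
  }
  num / pmax(den, 1e-12)
}

## ---- uniform fit/predict surface ---------------------------------------

#' Fit a machine-learning torque regressor
#'
#' Dispatches on `config$kind`:
#' * `"svr"`: Gaussian-kernel epsilon-SVR (via \pkg{e1071}); (C, gamma,
#'   epsilon) selected by grid search minimizing 8-fold cross-validated MSE.
#' * `"ann"`: two-hidden-layer tanh feed-forward network trained by BFGS
#'   quasi-Newton with early stopping and L2 regularization; best
#'   validation loss of 10 seeded restarts.
#' * `"lwpr"`: reduced locally-weighted-projection-regression variant —
#'   radial-basis receptive fields (kmeans-placed centers) each carrying a
#'   ridge-regularized local linear model, blended by normalized RBF
#'   weights; the distance metric is selected by 8-fold CV grid search. The
#'   substitution for a full incremental LWPR is recorded in the fitted
#'   model's metadata.
#'
#' All runs are reproducible given `config$seed`.
#'
#' @param problem A [regression_problem()] (decimated envelopes x torque).
#' @param config An [estimator_config()].
#' @return A list of class `fitted_estimator` with `kind`, the learned
#'   state, `selected` hyperparameters and `cv_score` (CV mean squared
#'   error, where applicable).
#' @export
fit_estimator <- function(problem, config) {
  stopifnot(inherits(problem, "regression_problem"),
            inherits(config, "estimator_config"))
  X <- problem$design
  y <- problem$response
  n <- nrow(X)
  if (n < config$folds)
    stop("fewer samples (", n, ") than cross-validation folds (",
         config$folds, ")")
  folds <- cv_folds(n, config$folds, config$seed)
  if (config$kind == "svr" && sd(y) == 0) {
    # libsvm scales the response; a constant target degenerates, so the
    # exact constant model is returned directly
    return(structure(list(kind = "svr",
                          model = list(constant = y[1]),
                          selected = list(), cv_score = 0,
                          meta = "constant-response shortcut",
                          n_features = ncol(X)),
                     class = "fitted_estimator"))
  }
  out <- switch(
    config$kind,
    svr = {
      grid <- expand.grid(C = config$svr_grid$C, gamma = config$svr_grid$gamma,
                          epsilon = config$svr_grid$epsilon)
      cv_mse <- vapply(seq_len(nrow(grid)), function(g) {
        errs <- vapply(seq_len(config$folds), function(f) {
          tr <- folds != f
          fit <- e1071::svm(X[tr, , drop = FALSE], y[tr],
                            type = "eps-regression", kernel = "radial",
                            cost = grid$C[g], gamma = grid$gamma[g],
                            epsilon = grid$epsilon[g], scale = TRUE)
          mean((predict(fit, X[!tr, , drop = FALSE]) - y[!tr])^2)
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      sel <- grid[which.min(cv_mse), ]
      fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                        cost = sel$C, gamma = sel$gamma,
                        epsilon = sel$epsilon, scale = TRUE)
      list(model = fit, selected = as.list(sel),
           cv_score = min(cv_mse), meta = "libsvm eps-regression")
    },
    ann = {
      model <- fit_ann(X, y, config)
      list(model = model,
           selected = list(hidden_sizes = config$ann$hidden_sizes,
                           reg = config$ann$reg),
           cv_score = model$val_loss,
           meta = "two-hidden-layer tanh MLP, BFGS, early stopping")
    },
    lwpr = {
      grid <- config$lwpr$distance_grid
      cv_mse <- vapply(seq_along(grid), function(g) {
        errs <- vapply(seq_len(config$folds), function(f) {
          tr <- folds != f
          fit <- fit_rf_net(X[tr, , drop = FALSE], y[tr], grid[g],
                            config$lwpr$n_fields, config$lwpr$ridge,
                            derive_seed(config$seed, g))
          mean((predict_rf_net(fit, X[!tr, , drop = FALSE]) - y[!tr])^2)
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      gsel <- which.min(cv_mse)
      fit <- fit_rf_net(X, y, grid[gsel], config$lwpr$n_fields,
                        config$lwpr$ridge, derive_seed(config$seed, gsel))
      list(model = fit, selected = list(distance = grid[gsel]),
           cv_score = min(cv_mse),
           meta = paste("reduced receptive-field weighted-linear-model",
                        "variant standing in for incremental LWPR"))
    })
  structure(list(kind = config$kind, model = out$model,
                 selected = out$selected, cv_score = out$cv_score,
                 meta = out$meta, n_features = ncol(X)),
            class = "fitted_estimator")
}

#' Predict torque with a fitted machine-learning estimator
#'
#' @param fitted A `fitted_estimator`.
#' @param design Envelope matrix with the same feature count as at fit time.
#' @return Finite torque predictions, one per row.
#' @export
estimator_predict <- function(fitted, design) {
  stopifnot(inherits(fitted, "fitted_estimator"))
  design <- as.matrix(design)
  if (ncol(design) != fitted$n_features)
    stop("design has ", ncol(design), " columns but fit used ",
         fitted$n_features)
  switch(fitted$kind,
         svr = if (!is.null(fitted$model$constant))
           rep(fitted$model$constant, nrow(design))
         else as.numeric(predict(fitted$model, design)),
         ann = predict_ann(fitted$model, design),
         lwpr = predict_rf_net(fitted$model, design))
}
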
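#' Construct a regression problem
#'
#' Pairs the N x M matrix of decimated SEMG envelopes (observations x
#' channels) with the N-vector of measured torques. No intercept column is
#' used anywhere: the regression model is torque = SEMG %*% beta + noise.
#'
#' @param design Numeric matrix, observations x channels.
#' @param response Numeric torque vector, N·m.
#' @return A list of class `regression_problem`.
#' @export
regression_problem <- function(design, response) {
  design <- as.matrix(design)
  response <- as.numeric(response)
  if (nrow(design) != length(response))
    stop("design rows and response length differ")
  if (anyNA(design) || anyNA(response)) stop("missing values not allowed")
  structure(list(design = design, response = response),
            class = "regression_problem")
}

#' Ordinary least squares fit (no intercept)
#'
#' Solves the normal equations beta = (X'X)^{-1} X'y via QR decomposition.
#' Errors on rank deficiency, naming the collinear columns.
#'
#' @param problem A [regression_problem()].
#' @return A list of class `linear_coefficients` with `beta` (named by
#'   channel), `lambda_used = 0`, and fit diagnostics (`sse`, `rank`).
#' @export
ols_fit <- function(problem) {
  stopifnot(inherits(problem, "regression_problem"))
  X <- problem$design
  y <- problem$response
  if (nrow(X) < ncol(X))
    stop("need at least as many observations as channels")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    if (is.null(bad)) bad <- qr_x$pivot[(qr_x$rank + 1):ncol(X)]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  resid <- y - X %*% beta
  # no-intercept fit sanity note: envelopes are nonnegative, torque roughly
  # zero-mean, so a large residual mean flags a misfit worth inspecting
  rng <- diff(range(y))
  if (rng > 0 && abs(mean(resid)) > 0.05 * rng)
    message("residual mean exceeds 5% of the torque range; ",
            "the no-intercept fit may be biased")
  structure(list(beta = as.numeric(beta), channel_names = colnames(X),
                 lambda_used = 0, sse = sum(resid^2), rank = qr_x$rank),
            class = "linear_coefficients")
}

# One-dimensional lasso soft-threshold: argmin lambda*|b| + sum (y - x b)^2.
soft_threshold <- function(z, t) sign(z) * max(abs(z) - t, 0)

#' l1-regularized least squares fit (lasso, no intercept)
#'
#' Minimizes lambda * sum_i |beta_i| + sum_t (y_t - x_t' beta)^2 by cyclic
#' coordinate descent (tolerance 1e-8 on the coefficient change, at most 1e5
#' sweeps). The problem is convex, so the solution is a global optimum;
#' lambda = 0 reproduces OLS on well-conditioned problems.
#'
#' @param problem A [regression_problem()].
#' @param lambda Nonnegative regularization parameter. Default 0.01.
#' @return A `linear_coefficients` list with `lambda_used = lambda`.
#' @export
rls_fit <- function(problem, lambda = 0.01) {
  stopifnot(inherits(problem, "regression_problem"))
  if (!is.numeric(lambda) || lambda < 0) stop("lambda must be nonnegative")
  X <- problem$design
  y <- problem$response
  m <- ncol(X)
  xx <- colSums(X^2)
  if (any(xx == 0)) {
    beta <- numeric(m)
    active <- xx > 0
    if (any(active)) {
      sub <- rls_fit(regression_problem(X[, active, drop = FALSE], y), lambda)
      beta[active] <- sub$beta
    }
    resid <- y - X %*% beta
    return(structure(list(beta = beta, channel_names = colnames(X),
                          lambda_used = lambda, sse = sum(resid^2),
                          rank = NA_integer_),
                     class = "linear_coefficients"))
  }
  beta <- numeric(m)
  resid <- y
  tol <- 1e-8
  for (sweep_i in seq_len(1e5)) {
    delta <- 0
    for (j in seq_len(m)) {
      bj_old <- beta[j]
      z <- sum(X[, j] * resid) + xx[j] * bj_old
      bj <- soft_threshold(z, lambda / 2) / xx[j]
      if (bj != bj_old) {
        resid <- resid - X[, j] * (bj - bj_old)
        delta <- max(delta, abs(bj - bj_old))
        beta[j] <- bj
      }
    }
    if (delta < tol) break
  }
  structure(list(beta = beta, channel_names = colnames(X),
                 lambda_used = lambda, sse = sum(resid^2),
                 rank = qr(X)$rank),
            class = "linear_coefficients")
}

#' Predict torque from linear coefficients
#'
#' @param coefs A `linear_coefficients` object.
#' @param design Envelope matrix with the same channel count (and order) as
#'   at fit time.
#' @return Torque predictions, N·m.
#' @export
linear_predict <- function(coefs, design) {
  stopifnot(inherits(coefs, "linear_coefficients"))
  design <- as.matrix(design)
  if (ncol(design) != length(coefs$beta))
    stop("design has ", ncol(design), " columns but fit used ",
         length(coefs$beta))
  as.numeric(design %*% coefs$beta)
}

#' Serialize linear coefficients to JSON
#'
#' Writes channel names, coefficients, lambda and fit diagnostics.
#'
#' @param coefs A `linear_coefficients` object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_coefficients <- function(coefs, path) {
  stopifnot(inherits(coefs, "linear_coefficients"))
  jsonlite::write_json(
    list(channel_names = coefs$channel_names, beta = coefs$beta,
         lambda = coefs$lambda_used, sse = coefs$sse, rank = coefs$rank),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
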
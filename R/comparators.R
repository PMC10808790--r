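# Competing models fitted to the same study table: Gaussian multiple
# linear regression and an S-shaped logistic alternative.

#' Fit the linear comparison model
#'
#' Ordinary least squares of the state on both predictors entered in
#' one step.  The reported log-likelihood is the Gaussian maximum:
#' `-n/2 * (log(2*pi*RSS/n) + 1)` with the MLE variance `RSS/n`, so the
#' model has `k = 4` free parameters (intercept, two slopes, sigma).
#'
#' @param data A [study_table()] or coercible data frame.
#' @return A `fit_result` with model `"linear"`.
#' @export
fit_linear <- function(data) {
  data <- as_study_table(data)
  v <- study_columns(data)
  n <- length(v$state)
  if (n < 5) stop_invalid("fit_linear() needs at least 5 rows")
  X <- cbind(1, v$asymmetry, v$bifurcation)
  if (qr(X)$rank < 3)
    stop_identifiability("design matrix is rank deficient")
  fit <- stats::lm(v$state ~ v$asymmetry + v$bifurcation)
  rss <- sum(stats::residuals(fit)^2)
  if (rss <= 0 || stats::sd(v$state) == 0)
    stop_numeric("degenerate linear fit: zero residual variance")
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  est <- c(intercept = unname(stats::coef(fit)[1]),
           slope_asymmetry = unname(stats::coef(fit)[2]),
           slope_bifurcation = unname(stats::coef(fit)[3]),
           sigma = sqrt(sigma2))
  # coefficient covariance from OLS theory; sigma by the delta method
  cov <- matrix(0, 4, 4, dimnames = list(names(est), names(est)))
  cov[1:3, 1:3] <- unname(stats::vcov(fit))
  cov[4, 4] <- sigma2 / (2 * n)
  new_fit_result(model = "linear", estimates = est, loglik = ll, k = 4L,
                 n = n, covariance = cov, converged = TRUE, n_starts = 1L,
                 best_objective = -ll, class = "linear_fit")
}

# Logistic comparator internals: the outcome is min-max rescaled to
# [0, 1] and modeled as mean 1/(1 + exp(-alpha_i/beta_i^2)) + Gaussian
# error; beta_i near zero is handled by a quadratic penalty (flagged).
logistic_mean <- function(par, x1, x2) {
  alpha <- par[1] + par[2] * x1
  beta <- par[3] + par[4] * x2
  stats::plogis(alpha / pmax(beta^2, 1e-12))
}

logistic_rss <- function(par, x1, x2, ys, penalty_env = NULL) {
  beta <- par[3] + par[4] * x2
  pen <- sum(pmax(0, 1e-3 - abs(beta))^2) * 1e4
  if (!is.null(penalty_env) && pen > 0) penalty_env$flagged <- TRUE
  rss <- sum((ys - logistic_mean(par, x1, x2))^2)
  if (!is.finite(rss)) return(1e10)
  rss + pen
}

#' Fit the logistic comparison model
#'
#' The S-shaped competitor: after min-max rescaling of the outcome to
#' `[0, 1]`, the mean response is `1/(1 + exp(-alpha_i/beta_i^2))` with
#' `alpha_i = a0 + a1*x1_i`, `beta_i = b0 + b1*x2_i` and Gaussian error
#' (`k = 5` free parameters).  The log-likelihood is reported in the
#' original outcome units via the change-of-variables Jacobian
#' `-n*log(range(Y))`, so it is directly comparable with the linear and
#' cusp fits.  Multi-start BFGS with the same seeding policy as
#' [fit_cusp()].
#'
#' @inheritParams fit_cusp
#' @return A `fit_result` with model `"logistic"`; `$penalized` flags
#'   whether the near-zero-beta barrier was ever active.
#' @export
fit_logistic <- function(data, n_starts = 10L, seed = 1L, maxit = 500L,
                         reltol = 1e-9) {
  data <- as_study_table(data)
  v <- study_columns(data)
  check_nonconstant(v)
  x1 <- v$asymmetry; x2 <- v$bifurcation; Y <- v$state
  n <- length(Y)
  rng <- range(Y)
  r <- diff(rng)
  if (r == 0) stop_numeric("degenerate logistic fit: constant outcome")
  ys <- (Y - rng[1]) / r

  # heuristic start: logit of the clipped rescaled outcome ~ predictors,
  # with a unit bifurcation submodel so alpha carries the trend
  eta <- stats::qlogis(pmin(pmax(ys, 0.02), 0.98))
  cf <- stats::coef(stats::lm(eta ~ x1 + x2))
  p0 <- c(a0 = unname(cf[1]), a1 = unname(cf[2]), b0 = 1, b1 = 0)
  starts <- list(p0)
  if (n_starts > 1) {
    starts <- c(starts, with_seed(seed, lapply(seq_len(n_starts - 1),
      function(i) p0 * (1 + 0.3 * stats::rnorm(4)) +
        c(0.3, 0.05, 0.3, 0.05) * stats::rnorm(4))))
  }
  env <- new.env()
  env$flagged <- FALSE
  fn <- function(p) logistic_rss(p, x1, x2, ys, env)
  runs <- lapply(starts, function(p)
    tryCatch(stats::optim(p, fn, method = "BFGS",
                          control = list(maxit = maxit, reltol = reltol)),
             error = function(e) list(par = p, value = Inf, convergence = 99L)))
  values <- vapply(runs, function(x) x$value, 0)
  if (all(!is.finite(values)))
    stop_numeric("logistic optimization failed for all starts")
  best <- runs[[which.min(values)]]
  par <- best$par
  rss <- sum((ys - logistic_mean(par, x1, x2))^2)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) - n * log(r)
  est <- c(par, sigma = sqrt(sigma2))
  names(est) <- c("a0", "a1", "b0", "b1", "sigma")

  # observed-information covariance on (a0, a1, b0, b1, sigma)
  nll5 <- function(q) {
    s <- q[5]
    if (s <= 0) return(1e10)
    res <- ys - logistic_mean(q[1:4], x1, x2)
    n * log(s) + sum(res^2) / (2 * s^2) + n / 2 * log(2 * pi) + n * log(r)
  }
  H <- tryCatch(stats::optimHess(est, nll5), error = function(e) NULL)
  cov <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (!is.null(cov) && any(diag(cov) <= 0)) cov <- NULL
  if (!is.null(cov)) dimnames(cov) <- list(names(est), names(est))

  new_fit_result(model = "logistic", estimates = est, loglik = ll, k = 5L,
                 n = n, covariance = cov,
                 converged = best$convergence == 0L,
                 n_starts = length(starts), best_objective = best$value,
                 start_values = values,
                 start_convergence = vapply(runs,
                   function(x) as.integer(x$convergence), 0L),
                 class = "logistic_fit",
                 extra = list(penalized = env$flagged, rescale = rng))
}
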
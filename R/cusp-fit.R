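# Maximum-likelihood cusp catastrophe regression:
# alpha_i = a0 + a1*x1_i, beta_i = b0 + b1*x2_i, z_i = w0 + w1*Y_i,
# with z_i following the stationary density exp(U(z; alpha, beta))/psi.

# ---- likelihood -----------------------------------------------------------
#
# All rows share one equispaced grid wide enough to cover every row's
# equilibria (|root| <= max(1, sqrt(|beta| + |alpha|))) plus a tail
# margin grown until the kernel at both grid ends is at least 40
# log-units below each row's maximum, so truncation error is ~exp(-40).
# Composite Simpson quadrature on n_grid (odd) points; the compiled
# kernel in src/cusp_nll.cpp produces the objective and the analytic
# score (which only needs the first two moments of each row's
# stationary density) in one pass.

# par = c(a0, a1, b0, b1, w0, w1); value and analytic gradient come out
# of one compiled pass (see src/cusp_nll.cpp), memoized on the last par
# so optim's separate fn/gr calls share the work.
cusp_nll_cache <- function(x1, x2, Y, n_grid = 401L) {
  last_par <- NULL
  last <- NULL
  function(par) {
    if (is.null(last_par) || !identical(as.numeric(par), last_par)) {
      last_par <<- as.numeric(par)
      last <<- .cusp_nll_gr_cpp(last_par, x1, x2, Y, n_grid)
    }
    last
  }
}

cusp_nll_raw <- function(par, x1, x2, Y, n_grid = 401L) {
  .cusp_nll_gr_cpp(as.numeric(par), x1, x2, Y, n_grid)$value
}

cusp_nll_grad <- function(par, x1, x2, Y, n_grid = 401L) {
  .cusp_nll_gr_cpp(as.numeric(par), x1, x2, Y, n_grid)$gradient
}

#' Negative log-likelihood of the cusp regression model
#'
#' For coefficients `(a0, a1, b0, b1, w0, w1)` and a study table, returns
#' `-sum_i [ U(z_i; alpha_i, beta_i) - log psi(alpha_i, beta_i) + log|w1| ]`.
#' The `log|w1|` Jacobian makes this a proper likelihood in the observed
#' outcome, so values are comparable with the linear and logistic
#' competitors fitted to the same data.
#'
#' @param coeffs Numeric vector of length 6, ordered
#'   `(a0, a1, b0, b1, w0, w1)` (names are ignored).
#' @param data A [study_table()].
#' @param n_grid Odd number of Simpson quadrature nodes per observation.
#' @return Scalar negative log-likelihood.
#' @export
cusp_negloglik <- function(coeffs, data, n_grid = 401L) {
  data <- as_study_table(data)
  if (length(coeffs) != 6 || !is.numeric(coeffs))
    stop_invalid("'coeffs' must be numeric of length 6")
  if (coeffs[6] == 0)
    stop_invalid("w1 must be nonzero")
  v <- study_columns(data)
  cusp_nll_raw(as.numeric(coeffs), v$asymmetry, v$bifurcation, v$state,
               n_grid = n_grid)
}

# ---- fitting --------------------------------------------------------------

# Linear-regression-inspired starting point: regress the standardized
# outcome on both predictors; slopes seed a1 and b1, the outcome
# mean/SD seed w0 and w1; intercepts center alpha and beta near zero.
cusp_start_heuristic <- function(x1, x2, Y) {
  sY <- stats::sd(Y)
  z0 <- (Y - mean(Y)) / sY
  cf <- stats::coef(stats::lm(z0 ~ x1 + x2))
  a1 <- unname(cf[2])
  b1 <- unname(cf[3])
  c(a0 = -a1 * mean(x1), a1 = a1,
    b0 = -0.25 - b1 * mean(x2), b1 = b1,
    w0 = -mean(Y) / sY, w1 = 1 / sY)
}

#' Fit the cusp catastrophe regression model by maximum likelihood
#'
#' Minimizes [cusp_negloglik()] by quasi-Newton (BFGS) iteration with an
#' analytic gradient, from a linear-regression-based starting point plus
#' `n_starts - 1` seeded random perturbations of it (the objective
#' surface can be multimodal).  The reported optimum is the best across
#' starts and is never worse than the objective at the heuristic start.
#' The sign indeterminacy `(a, w) -> (-a, -w)` is resolved by reporting
#' `w1 > 0`; Wald inference comes from the inverse observed Hessian.
#'
#' @param data A [study_table()] (or data frame coercible to one) with at
#'   least 20 rows and non-constant state, asymmetry and bifurcation
#'   columns.
#' @param n_starts Total number of starts (heuristic + random), >= 1.
#' @param seed Integer seed for the random perturbations.
#' @param n_grid Odd number of Simpson quadrature nodes.
#' @param maxit Per-start iteration cap.
#' @param reltol Relative objective-change convergence tolerance.
#' @return A `cusp_fit` object (also of class `fit_result`): estimates,
#'   `loglik`, `k = 6`, `n`, covariance, per-coefficient Wald inference,
#'   convergence metadata.
#' @export
fit_cusp <- function(data, n_starts = 10L, seed = 1L, n_grid = 401L,
                     maxit = 500L, reltol = 1e-9) {
  data <- as_study_table(data)
  v <- study_columns(data)
  check_nonconstant(v)
  if (length(v$state) < 20)
    stop_invalid("fit_cusp() needs at least 20 complete rows")
  x1 <- v$asymmetry; x2 <- v$bifurcation; Y <- v$state

  p0 <- cusp_start_heuristic(x1, x2, Y)
  starts <- list(p0)
  if (n_starts > 1) {
    pert <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i) {
      p <- p0 * (1 + 0.3 * stats::rnorm(6)) +
        c(0.3, 0.05, 0.3, 0.05, 0.3, 0) * stats::rnorm(6)
      p[6] <- p0[6] * exp(0.4 * stats::rnorm(1))
      p
    }))
    starts <- c(starts, pert)
  }

  cache <- cusp_nll_cache(x1, x2, Y, n_grid = n_grid)
  fn <- function(p) cache(p)$value
  gr <- function(p) cache(p)$gradient

  runs <- lapply(starts, function(p) {
    tryCatch(stats::optim(p, fn, gr, method = "BFGS",
                          control = list(maxit = maxit, reltol = reltol)),
             error = function(e) list(par = p, value = Inf, convergence = 99L,
                                      message = conditionMessage(e)))
  })
  values <- vapply(runs, function(r) r$value, 0)
  if (all(!is.finite(values))) {
    diag_tab <- data.frame(start = seq_along(runs), value = values,
      convergence = vapply(runs, function(r) as.integer(r$convergence), 0L))
    stop_numeric(paste0("cusp optimization failed for all ", length(runs),
                        " starts; per-start diagnostics:\n",
                        paste(utils::capture.output(print(diag_tab)),
                              collapse = "\n")))
  }
  best <- runs[[which.min(values)]]
  par <- best$par
  if (par[6] < 0) par <- par * c(-1, -1, 1, 1, -1, -1)  # canonical w1 > 0
  names(par) <- c("a0", "a1", "b0", "b1", "w0", "w1")

  H <- tryCatch(stats::optimHess(par, fn, gr), error = function(e) NULL)
  cov <- NULL
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov) && any(diag(cov) <= 0)) cov <- NULL
    if (!is.null(cov)) dimnames(cov) <- list(names(par), names(par))
  }
  if (is.null(cov))
    warning("observed Hessian is singular or indefinite; ",
            "Wald inference unavailable", call. = FALSE)

  new_fit_result(
    model = "cusp", estimates = par, loglik = -best$value, k = 6L,
    n = length(Y), covariance = cov,
    converged = best$convergence == 0L,
    n_starts = length(starts), best_objective = best$value,
    start_values = values,
    start_convergence = vapply(runs, function(r) as.integer(r$convergence), 0L),
    class = "cusp_fit")
}

# ---- shared fit-result container ------------------------------------------

new_fit_result <- function(model, estimates, loglik, k, n, covariance,
                           converged, n_starts, best_objective,
                           start_values = NULL, start_convergence = NULL,
                           class = character(), extra = list()) {
  se <- z <- p <- rep(NA_real_, length(estimates))
  if (!is.null(covariance)) {
    idx <- match(names(estimates), colnames(covariance))
    ok <- !is.na(idx)
    se[ok] <- sqrt(diag(covariance))[idx[ok]]
    z <- estimates / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  out <- c(list(
    model = model, estimates = estimates, loglik = loglik, k = as.integer(k),
    n = as.integer(n), covariance = covariance, se = se, z = z, p = p,
    ci95_low = estimates - 1.96 * se, ci95_high = estimates + 1.96 * se,
    converged = converged, n_starts = as.integer(n_starts),
    best_objective = best_objective, start_values = start_values,
    start_convergence = start_convergence), extra)
  structure(out, class = c(class, "fit_result"))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s model fit: n = %d, k = %d, loglik = %.3f (converged: %s)\n",
              x$model, x$n, x$k, x$loglik, x$converged))
  print(wald_table(x, warn = FALSE), digits = 4)
  invisible(x)
}

#' Wald inference table for a fitted model
#'
#' Per-coefficient standard errors, z statistics, two-sided normal
#' p-values, 95% confidence intervals, and a significance flag at the
#' configured level (default 0.01, matching the analysis policy for
#' large survey samples).
#'
#' @param fit A `fit_result` (from [fit_cusp()], [fit_linear()] or
#'   [fit_logistic()]).
#' @param significance Flagging level in (0, 0.5).
#' @param warn Warn when the covariance was unavailable.
#' @return A data frame with one row per coefficient.
#' @export
wald_table <- function(fit, significance = 0.01, warn = TRUE) {
  stopifnot(inherits(fit, "fit_result"))
  if (!(significance > 0 && significance < 0.5))
    stop_invalid("'significance' must be in (0, 0.5)")
  if (is.null(fit$covariance) && warn)
    warning("covariance unavailable; inference columns are NA", call. = FALSE)
  data.frame(
    term = names(fit$estimates),
    estimate = unname(fit$estimates),
    ci95_low = unname(fit$ci95_low),
    ci95_high = unname(fit$ci95_high),
    se = unname(fit$se),
    z = unname(fit$z),
    p = unname(fit$p),
    significant = ifelse(is.na(fit$p), NA, fit$p < significance),
    row.names = NULL)
}
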
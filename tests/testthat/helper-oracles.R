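# Independent oracles used across the suite.  Each recomputes its
# quantity by a different route than the implementation under test.

# Normalizing constant by dense-grid trapezoid integration.
psi_trapezoid <- function(alpha, beta, lim = 12, n_grid = 200001L) {
  y <- seq(-lim, lim, length.out = n_grid)
  u <- alpha * y + 0.5 * beta * y^2 - 0.25 * y^4
  f <- exp(u)
  h <- y[2] - y[1]
  h * (sum(f) - (f[1] + f[n_grid]) / 2)
}

# Raw moments of the cusp stationary density by the same grid.
moment_trapezoid <- function(alpha, beta, k, lim = 12, n_grid = 200001L) {
  y <- seq(-lim, lim, length.out = n_grid)
  f <- exp(alpha * y + 0.5 * beta * y^2 - 0.25 * y^4)
  h <- y[2] - y[1]
  num <- h * (sum(y^k * f) - (y[1]^k * f[1] + y[n_grid]^k * f[n_grid]) / 2)
  den <- h * (sum(f) - (f[1] + f[n_grid]) / 2)
  num / den
}

# Rejection sampler for the cusp stationary density: uniform proposal
# on the truncated support with a constant envelope at the density max.
rejection_sample_cusp <- function(alpha, beta, n, seed, lim = 8) {
  set.seed(seed)
  y <- seq(-lim, lim, length.out = 4001L)
  u <- alpha * y + 0.5 * beta * y^2 - 0.25 * y^4
  umax <- max(u)
  out <- numeric(0)
  while (length(out) < n) {
    m <- 4L * n
    cand <- stats::runif(m, -lim, lim)
    ucand <- alpha * cand + 0.5 * beta * cand^2 - 0.25 * cand^4
    keep <- stats::runif(m) < exp(ucand - umax)
    out <- c(out, cand[keep])
  }
  out[seq_len(n)]
}

# OLS by direct normal equations.
ols_normal_equations <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# Dip statistic oracle: discretized linear program over piecewise-linear
# unimodal CDFs with the mode gap enumerated (grid: data values,
# left-limit points, subdivided inter-data gaps).  Solved with scipy's
# HiGHS via the system Python.  A lower bound on the dip, approaching
# it from below with O(subsegment width) mode-smearing bias.
dip_lp_oracle_batch <- function(samples, n_mid = 30L) {
  fin <- tempfile(fileext = ".json")
  jsonlite::write_json(samples, fin, digits = NA)
  script <- testthat::test_path("dip-lp-oracle.py")
  out <- system2("python", c(shQuote(script), shQuote(fin), n_mid),
                 stdout = TRUE)
  unlist(jsonlite::fromJSON(out[length(out)]))
}

# Study-scale generating truth used throughout the recovery tests.
reading_truth <- c(a0 = -3.015, a1 = 0.331, b0 = -1.453, b1 = 0.112,
                   w0 = -3.522, w1 = 0.364)
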
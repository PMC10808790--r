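# Cusp regression likelihood and maximum-likelihood fitting.

tiny_table <- function(Y, x1, x2) {
  study_table(data.frame(engagement = Y, liking = x1, disorder = x2))
}

test_that("negative log-likelihood matches the quadrature oracle", {
  # single row (Y = 0, x1 = 0, x2 = 0), coefficients (0,1,0,1,0,1):
  # z = 0, alpha = 0, beta = 0, so NLL = log psi(0, 0)
  tab <- tiny_table(c(0, 1), c(0, 1), c(0, 1))
  nll2 <- cusp_negloglik(c(0, 1, 0, 1, 0, 1), tab)
  manual <- -sum(vapply(1:2, function(i) {
    z <- tab$data$engagement[i]
    a <- tab$data$liking[i]
    b <- tab$data$disorder[i]
    a * z + 0.5 * b * z^2 - 0.25 * z^4 - log(psi_trapezoid(a, b))
  }, 0))
  expect_equal(nll2, manual, tolerance = 1e-7)
  expect_equal(cusp_negloglik(c(0, 1, 0, 1, 0, 1), tiny_table(0, 0, 0)),
               log(psi_trapezoid(0, 0)), tolerance = 1e-7)
  expect_error(cusp_negloglik(c(0, 1, 0, 1, 0, 0), tab),
               class = "cuspfit_invalid_error")
})

test_that("likelihood is invariant under the documented symmetries", {
  set.seed(21)
  tab <- generate_study(cusp_study_spec(n = 60), seed = 21)
  th <- c(-2.5, 0.3, -1.2, 0.1, -3.2, 0.35)
  flip <- th * c(-1, -1, 1, 1, -1, -1)
  expect_equal(cusp_negloglik(th, tab), cusp_negloglik(flip, tab),
               tolerance = 1e-9)
  # shifting Y by c while replacing w0 by w0 - w1*c changes nothing
  d2 <- tab$data
  d2$engagement <- d2$engagement + 3
  tab2 <- study_table(d2)
  th2 <- th; th2[5] <- th[5] - th[6] * 3
  expect_equal(cusp_negloglik(th, tab), cusp_negloglik(th2, tab2),
               tolerance = 1e-9)
})

test_that("analytic gradient matches central differences", {
  set.seed(22)
  tab <- generate_study(cusp_study_spec(n = 80), seed = 22)
  v <- cuspfit:::study_columns(tab)
  th <- c(-2.8, 0.3, -1.3, 0.1, -3.4, 0.36)
  g <- cuspfit:::cusp_nll_grad(th, v$asymmetry, v$bifurcation, v$state)
  gn <- vapply(1:6, function(j) {
    h <- 1e-5 * max(1, abs(th[j]))
    e <- replace(numeric(6), j, h)
    (cuspfit:::cusp_nll_raw(th + e, v$asymmetry, v$bifurcation, v$state) -
     cuspfit:::cusp_nll_raw(th - e, v$asymmetry, v$bifurcation, v$state)) /
      (2 * h)
  }, 0)
  expect_equal(g, gn, tolerance = 1e-5)
})

test_that("fitting honours the optimizer contract and canonical form", {
  tab <- generate_study(cusp_study_spec(n = 300), seed = 31)
  v <- cuspfit:::study_columns(tab)
  fit <- fit_cusp(tab, n_starts = 3, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$k, 6L)
  expect_equal(fit$n, 300L)
  expect_gt(fit$estimates[["w1"]], 0)
  p0 <- cuspfit:::cusp_start_heuristic(v$asymmetry, v$bifurcation, v$state)
  nll0 <- cuspfit:::cusp_nll_raw(p0, v$asymmetry, v$bifurcation, v$state)
  expect_lte(fit$best_objective, nll0)
  expect_equal(fit$loglik, -fit$best_objective)
  # covariance is symmetric PSD with matching standard errors
  expect_equal(fit$covariance, t(fit$covariance), tolerance = 1e-8)
  expect_true(all(eigen(fit$covariance, only.values = TRUE)$values > 0))
  expect_equal(fit$se, sqrt(diag(fit$covariance)),
               ignore_attr = TRUE)
})

test_that("moderate-n fits recover the generating coefficients loosely", {
  ests <- t(vapply(1:3, function(r) {
    tab <- generate_study(cusp_study_spec(n = 500), seed = 600 + r)
    fit_cusp(tab, n_starts = 2, seed = r)$estimates
  }, numeric(6)))
  m <- colMeans(ests)
  expect_equal(m[["a1"]], reading_truth[["a1"]], tolerance = 0.25)
  expect_equal(m[["w1"]], reading_truth[["w1"]], tolerance = 0.15)
  expect_lt(abs(m[["b1"]] - reading_truth[["b1"]]), 0.08)
})

test_that("reported standard errors are calibrated against replicate spread", {
  res <- lapply(1:24, function(r) {
    tab <- generate_study(cusp_study_spec(n = 1000), seed = 7100 + r)
    fit <- fit_cusp(tab, n_starts = 2, seed = r)
    list(est = fit$estimates, se = fit$se)
  })
  est <- t(vapply(res, function(x) x$est, numeric(6)))
  se <- t(vapply(res, function(x) x$se, numeric(6)))
  ratio <- apply(est, 2, sd) / colMeans(se, na.rm = TRUE)
  expect_true(all(ratio > 0.7 & ratio < 1.3),
              label = paste("SD/mean-SE ratios:",
                            paste(round(ratio, 2), collapse = " ")))
})

test_that("degenerate inputs raise identifiability errors", {
  d <- data.frame(engagement = rnorm(30), liking = rnorm(30), disorder = 5)
  suppressWarnings(tab <- study_table(d))
  expect_error(fit_cusp(tab), class = "cuspfit_identifiability_error")
  small <- generate_study(cusp_study_spec(n = 10), seed = 1)
  expect_error(fit_cusp(small), class = "cuspfit_invalid_error")
})

test_that("wald_table computes normal-theory inference columns", {
  fit <- structure(list(
    model = "cusp",
    estimates = c(a1 = 0.331, b1 = 0.112, zero = 0),
    se = c(0.028, 0.005, 0.1),
    z = c(0.331 / 0.028, 0.112 / 0.005, 0),
    p = 2 * pnorm(-abs(c(0.331 / 0.028, 0.112 / 0.005, 0))),
    ci95_low = c(0.331, 0.112, 0) - 1.96 * c(0.028, 0.005, 0.1),
    ci95_high = c(0.331, 0.112, 0) + 1.96 * c(0.028, 0.005, 0.1),
    covariance = diag(c(0.028, 0.005, 0.1)^2),
    loglik = 0, k = 3L, n = 100L, converged = TRUE),
    class = "fit_result")
  w <- wald_table(fit, significance = 0.01)
  expect_equal(w$z[1], 11.82, tolerance = 0.001)
  expect_equal(w$ci95_low[1], 0.276, tolerance = 0.002)
  expect_equal(w$ci95_high[1], 0.386, tolerance = 0.002)
  expect_equal(w$ci95_low[2], 0.102, tolerance = 0.002)
  expect_equal(w$ci95_high[2], 0.122, tolerance = 0.002)
  # zero estimate: z = 0, p = 1, not significant
  expect_equal(w$z[3], 0)
  expect_equal(w$p[3], 1)
  expect_false(w$significant[3])
  expect_true(all(w$significant[1:2]))
  expect_error(wald_table(fit, significance = 0.7),
               class = "cuspfit_invalid_error")
})
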
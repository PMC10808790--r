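# Core mathematics of the cusp stationary density.

test_that("kernel evaluates the quartic potential exactly", {
  expect_identical(cusp_kernel(0, 5, -3), 0)
  expect_equal(cusp_kernel(1, 1, 2), 1.75)
  expect_equal(cusp_kernel(2, 0, 0), -4)
  # vectorized with recycling
  expect_equal(cusp_kernel(c(0, 1, 2), c(5, 1, 0), c(-3, 2, 0)),
               c(0, 1.75, -4))
  expect_error(cusp_kernel(Inf, 0, 0), class = "cuspfit_invalid_error")
  expect_error(cusp_kernel(0, NA, 0), class = "cuspfit_invalid_error")
})

test_that("normalizing constant matches closed forms and symmetry", {
  expect_equal(cusp_psi(0, 0), 2^(-1 / 2) * gamma(1 / 4), tolerance = 1e-8)
  expect_equal(cusp_psi(0, 0), psi_trapezoid(0, 0), tolerance = 1e-7)
  expect_equal(cusp_psi(3, 1), cusp_psi(-3, 1), tolerance = 1e-10)
  # Gaussian limit at strongly negative beta
  expect_equal(cusp_psi(0, -10), sqrt(2 * pi / 10), tolerance = 0.01)
  expect_equal(cusp_psi(0, -10), psi_trapezoid(0, -10), tolerance = 1e-7)
  expect_error(cusp_psi(0, 0, rel_tol = 0.1), class = "cuspfit_invalid_error")
})

test_that("density normalizes to one over random control points", {
  set.seed(11)
  for (i in 1:100) {
    a <- stats::runif(1, -3, 3)
    b <- stats::runif(1, -3, 3)
    psi <- cusp_psi(a, b)
    expect_equal(psi_trapezoid(a, b) / psi, 1, tolerance = 1e-6)
  }
})

test_that("equilibria solve the cubic with correct stability and region", {
  eq <- cusp_equilibria(0, 1)
  expect_equal(eq$roots, c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(eq$stability, c("stable", "antimode", "stable"))
  expect_equal(eq$region, "bimodal")
  expect_equal(eq$delta, -4)

  eq2 <- cusp_equilibria(2, 0)
  expect_equal(eq2$roots, 2^(1 / 3), tolerance = 1e-12)
  expect_equal(eq2$region, "unimodal")
  expect_equal(eq2$delta, 108)

  eq0 <- cusp_equilibria(0, 0)
  expect_equal(eq0$roots, 0)
  expect_equal(eq0$region, "boundary")
})

test_that("region classification matches brute-force root counting", {
  set.seed(7)
  for (i in 1:1000) {
    a <- stats::runif(1, -3, 3)
    b <- stats::runif(1, -3, 3)
    r <- polyroot(c(a, b, 0, -1))        # alpha + beta*y - y^3
    n_real <- sum(abs(Im(r)) < 1e-8)
    cls <- cusp_classify(a, b)
    if (cls == "bimodal") expect_equal(n_real, 3)
    if (cls == "unimodal") expect_equal(n_real, 1)
    eq <- cusp_equilibria(a, b)
    expect_true(all(abs(a + b * eq$roots - eq$roots^3) < 1e-10))
  }
})

test_that("density maxima coincide with stable roots", {
  set.seed(3)
  for (i in 1:25) {
    a <- stats::runif(1, -2, 2)
    b <- stats::runif(1, -2, 3)
    eq <- cusp_equilibria(a, b)
    stable <- eq$roots[eq$stability == "stable"]
    y <- seq(-4, 4, length.out = 40001)
    dens <- cusp_kernel(y, a, b)
    pk <- which(diff(sign(diff(dens))) == -2) + 1
    # polish each grid peak to quadrature precision before comparing
    grid_modes <- vapply(pk, function(j)
      stats::optimize(function(t) cusp_kernel(t, a, b),
                      c(y[j - 1], y[j + 1]), maximum = TRUE,
                      tol = 1e-10)$maximum, 0)
    if (eq$region == "bimodal" && length(grid_modes) == length(stable))
      expect_equal(sort(grid_modes), sort(stable), tolerance = 1e-6)
    if (eq$region == "unimodal")
      expect_equal(grid_modes, stable, tolerance = 1e-6)
  }
})

test_that("density is symmetric under (y, alpha) sign flip", {
  y <- seq(-3, 3, by = 0.25)
  for (b in c(-2, 0, 1.5)) {
    expect_equal(cusp_density(y, 1.2, b), cusp_density(-y, -1.2, b),
                 tolerance = 1e-10)
  }
})

test_that("Gaussian limit: variance approaches -1/beta", {
  v <- moment_trapezoid(0, -12, 2)
  expect_equal(v, 1 / 12, tolerance = 0.02)
  # quadrature-based mean prediction agrees
  expect_equal(cusp_predict(0, -12, "mean"), 0, tolerance = 1e-8)
})

test_that("prediction conventions behave as documented", {
  expect_equal(cusp_predict(0, 1, "delay", previous_state = 0.9), 1)
  expect_equal(cusp_predict(0, 1, "delay", previous_state = -0.2), -1)
  expect_error(cusp_predict(0, 1, "delay"), class = "cuspfit_invalid_error")
  expect_gt(cusp_predict(0.1, 1, "maxwell"), 0)
  # exact tie: positive root returned with ambiguity flag
  tie <- cusp_predict(0, 5, "maxwell")
  expect_gt(tie, 0)
  expect_true(isTRUE(attr(tie, "ambiguous")))
  expect_equal(cusp_predict(0, 5, "mean"), 0, tolerance = 1e-8)
})
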
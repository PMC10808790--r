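# Synthetic-data generator: exact sampling from the stationary density
# and study-table assembly.

test_that("sampler moments match quadrature in the Gaussian regime", {
  s <- sample_cusp_state(0, -10, 1e4, seed = 7)
  expect_lt(abs(mean(s)), 0.02)
  v_quad <- moment_trapezoid(0, -10, 2)
  expect_equal(var(s), v_quad, tolerance = 0.05)
})

test_that("sampler respects symmetry in the bimodal regime", {
  s <- sample_cusp_state(0, 4, 1e4, seed = 8)
  expect_equal(mean(s > 0), 0.5, tolerance = 0.02)
})

test_that("sampler agrees with a rejection-sampler oracle (KS)", {
  set.seed(31)
  for (i in 1:10) {
    a <- stats::runif(1, -2, 2)
    b <- stats::runif(1, -2, 3)
    s1 <- sample_cusp_state(a, b, 5000, seed = 100 + i)
    s2 <- rejection_sample_cusp(a, b, 5000, seed = 200 + i)
    ks <- suppressWarnings(stats::ks.test(s1, s2))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("sampling is deterministic under a fixed seed", {
  s1 <- sample_cusp_state(0.5, 1, 100, seed = 42)
  s2 <- sample_cusp_state(0.5, 1, 100, seed = 42)
  expect_identical(s1, s2)
  t1 <- generate_study(cusp_study_spec(n = 50), seed = 9)
  t2 <- generate_study(cusp_study_spec(n = 50), seed = 9)
  expect_identical(t1$data, t2$data)
})

test_that("generated studies have the documented structure", {
  spec <- cusp_study_spec()
  tab <- generate_study(spec, seed = 4)
  expect_equal(tab$n_analyzed, 2420)
  expect_named(tab$data, c("engagement", "liking", "disorder"))
  expect_length(tab$deletion_log, 0)
  # back-transform identity: w0 + w1*Y reproduces the sampled z exactly
  cf <- spec$coefficients
  z <- attr(tab, "z")
  expect_equal(cf[["w0"]] + cf[["w1"]] * tab$data$engagement, z,
               tolerance = 1e-12)
  # predictors on the PIRLS-like scale
  expect_equal(mean(tab$data$liking), 10, tolerance = 0.2)
  expect_equal(sd(tab$data$disorder), 2, tolerance = 0.2)
  # region metadata present and consistent with the control submodels
  region <- attr(tab, "region")
  expect_length(region, 2420)
  alpha <- cf[["a0"]] + cf[["a1"]] * tab$data$liking
  beta <- cf[["b0"]] + cf[["b1"]] * tab$data$disorder
  expect_identical(region, cusp_classify(alpha, beta))
})

test_that("a small minority of rows falls inside the bifurcation set", {
  counts <- vapply(1:5, function(i) {
    tab <- generate_study(cusp_study_spec(), seed = 400 + i)
    sum(attr(tab, "region") == "bimodal")
  }, 0L)
  expect_gt(sum(counts), 0)                 # occupied across seeds...
  expect_lt(max(counts), 0.05 * 2420)       # ...but sparsely
})

test_that("missingness injection exercises listwise deletion", {
  spec <- cusp_study_spec(n = 500, missing_rate = 0.02)
  tab <- generate_study(spec, seed = 11)
  expect_lt(tab$n_analyzed, 500)
  expect_equal(tab$n_analyzed + length(tab$deletion_log), 500)
})

test_that("specs validate their inputs", {
  expect_error(cusp_study_spec(n = 0))
  expect_error(cusp_study_spec(predictor_correlation = 1))
  expect_error(cusp_study_spec(coefficients = c(0, 1, 0, 1, 0, 0)),
               class = "cuspfit_invalid_error")
})

test_that("study CSV export round-trips", {
  tab <- generate_study(cusp_study_spec(n = 40), seed = 2)
  f <- tempfile(fileext = ".csv")
  write_study_csv(tab, f)
  back <- read_study_table(f)
  expect_equal(back$data, tab$data, tolerance = 1e-12)
})
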
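# Dip test, Silverman critical bandwidth, mode counting, SiZer.

test_that("dip statistic reproduces closed-form values exactly", {
  expect_equal(dip_statistic(c(0, 1)), 0.25, tolerance = 1e-12)
  expect_equal(dip_statistic(c(0, 0, 1)), 1 / 6, tolerance = 1e-12)
  # equally spaced samples sit exactly at the lower bound 1/(2n)
  for (n in c(4, 8, 17)) {
    expect_equal(dip_statistic(seq_len(n)), 1 / (2 * n), tolerance = 1e-9)
  }
  expect_equal(dip_statistic(rep(3.7, 12)), 0)
  expect_error(dip_statistic(1), class = "cuspfit_invalid_error")
  expect_error(dip_statistic(c(1, NA)), class = "cuspfit_invalid_error")
})

test_that("dip statistic agrees with the unimodal-CDF linear program", {
  cases <- list(c(0, 1),
                c(0, 0.01, 1, 1.01),
                c(0, 0.21, 0.93, 0.93),
                c(0.11, 0.06, 0.83, 0.58, 0.47),
                c(-2.0396, -1.557, 1.9349),
                c(0.15, 0.03, 0.48, 0.44, 0.06, 0.33, 0.88, 0.93),
                c(-0.56, 0.7861, -1.1307, -1.6152, -1.2143, 0.6168,
                  0.0429, -0.1439))
  d_lp <- dip_lp_oracle_batch(cases)
  d_impl <- vapply(cases, dip_statistic, 0)
  # the LP relaxes the point mode over a small gap, so it approaches
  # the dip from below
  expect_true(all(d_lp <= d_impl + 1e-7))
  expect_true(all(d_impl - d_lp < 4e-3))
})

test_that("dip never falls below 1/(2n) for non-degenerate samples", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(2:60, 1)
    x <- switch(sample(1:3, 1), rnorm(n), runif(n),
                c(rnorm(ceiling(n / 2), -3), rnorm(floor(n / 2), 3)))
    expect_gte(dip_statistic(x), 1 / (2 * n) - 1e-12)
    expect_lte(dip_statistic(x), 0.25 + 1e-12)
  }
})

test_that("dip test separates bimodal mixtures from uniform samples", {
  set.seed(1)
  mix <- c(rnorm(250, -3), rnorm(250, 3))
  expect_gt(dip_statistic(mix), 0.05)
  dt <- dip_test(mix, n_mc = 1999, seed = 3)
  expect_lt(dt$p, 0.001)
  set.seed(2)
  u <- runif(500)
  du <- dip_test(u, n_mc = 999, seed = 4)
  expect_gt(du$p, 0.05)
  # bit-for-bit reproducible under a fixed seed
  du2 <- dip_test(u, n_mc = 999, seed = 4)
  expect_identical(du, du2)
})

test_that("critical bandwidth of the two-point sample is one", {
  # for equal Gaussians at +/-1 the mixture is unimodal iff h >= 1
  h <- cuspfit:::critical_bandwidth(c(-1, 1), k = 1)
  expect_equal(h, 1, tolerance = 2e-3)
})

test_that("critical bandwidth is monotone in the null mode count", {
  set.seed(6)
  x <- c(rnorm(120, -2), rnorm(120, 2), rnorm(60, 6))
  h1 <- cuspfit:::critical_bandwidth(x, 1)
  h2 <- cuspfit:::critical_bandwidth(x, 2)
  h3 <- cuspfit:::critical_bandwidth(x, 3)
  expect_lte(h2, h1)
  expect_lte(h3, h2)
  # mode counts bracket the critical bandwidth
  expect_lte(count_modes(x, h1), 1)
  expect_gt(count_modes(x, h1 * 0.97), 1)
})

test_that("count_modes matches direct KDE evaluation", {
  expect_equal(count_modes(c(-1, 1), bandwidth = 0.3), 2L)
  expect_equal(count_modes(c(-1, 1), bandwidth = 2), 1L)
  expect_equal(count_modes(rep(5, 10)), 1L)
  set.seed(9)
  x <- c(rnorm(100, -3), rnorm(100, 3))
  expect_equal(count_modes(x, bandwidth = 0.5), 2L)
  expect_equal(count_modes(x, bandwidth = 5), 1L)
})

test_that("Silverman test rejects mixtures and retains Gaussian nulls", {
  set.seed(10)
  mix <- c(rnorm(150, -3), rnorm(150, 3))
  st <- silverman_test(mix, k_null = 1, n_boot = 300, seed = 5)
  expect_lt(st$p, 0.05)
  g <- rnorm(500)
  sg <- silverman_test(g, k_null = 1, n_boot = 300, seed = 6)
  expect_gt(sg$p, 0.05)
  # ladder stops at the first non-rejected k
  lad <- silverman_ladder(mix, level = 0.05, n_boot = 200, seed = 7)
  expect_gte(lad$k_selected, 2)
  expect_equal(nrow(lad$table), lad$k_selected)
})

test_that("SiZer classifies slopes of a symmetric unimodal density", {
  set.seed(13)
  x <- rnorm(1000)
  sz <- sizer_map(x, n_loc = 51, n_bw = 11)
  expect_equal(dim(sz$class), c(11L, 51L))
  expect_true(all(sz$class %in% c("increasing", "decreasing", "zero",
                                  "insufficient-data")))
  top <- sz$class[11, ]                   # largest bandwidth
  left <- top[sz$x < -0.5]
  right <- top[sz$x > 0.5]
  expect_gt(mean(left == "increasing"), 0.8)
  expect_gt(mean(right == "decreasing"), 0.8)
})

test_that("SiZer sees a right-loaded density as mostly increasing", {
  set.seed(14)
  x <- rbeta(1000, 5, 1.2)
  sz <- sizer_map(x, n_loc = 51, n_bw = 11)
  top <- sz$class[11, ]
  expect_gt(mean(top == "increasing"), 0.5)
})
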
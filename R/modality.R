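# Multimodality test battery for the outcome variable: Hartigan dip
# test, Silverman critical-bandwidth test, kernel mode counting, and a
# simplified SiZer map.

#' Hartigan's dip statistic
#'
#' The largest sup-distance reduction achievable by the best-fitting
#' unimodal CDF: `D = inf_G sup_x |F_n(x) - G(x)|` over CDFs `G` that
#' are convex up to a mode and concave after it.  Computed exactly (to
#' bisection tolerance ~1e-15) from the corridor/convex-hull
#' characterization of the feasibility problem.  `D >= 1/(2n)` for any
#' sample with at least two distinct values.
#'
#' @param x Numeric sample (n >= 2, finite).
#' @return The dip statistic, a scalar in `[0, 0.25]`.
#' @examples
#' dip_statistic(c(0, 1))  # 0.25
#' @export
dip_statistic <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    stop_invalid("dip_statistic() needs a numeric sample with n >= 2")
  if (anyNA(x) || any(!is.finite(x)))
    stop_invalid("non-finite values in sample")
  .dip_stat_cpp(sort(x))
}

#' Monte-Carlo dip test for unimodality
#'
#' The null distribution is simulated from uniform(0, 1) samples of the
#' same size (the least favorable unimodal null), seeded and
#' reproducible; `p = (1 + #{D_mc >= D_obs}) / (n_mc + 1)` with the +1
#' continuity correction.
#'
#' @param x Numeric sample (n >= 4).
#' @param n_mc Number of Monte-Carlo null replicates.
#' @param seed Integer seed for the null simulation.
#' @return A list of class `"dip_test"`: `D`, `p`, `n`, `n_mc`, `seed`.
#' @export
dip_test <- function(x, n_mc = 9999L, seed = 1L) {
  if (length(x) < 4) stop_invalid("dip_test() needs n >= 4")
  D <- dip_statistic(x)
  n <- length(x)
  null_D <- with_seed(seed, vapply(seq_len(n_mc), function(b)
    .dip_stat_cpp(sort(stats::runif(n)), 1e-9), 0))
  p <- (1 + sum(null_D >= D)) / (n_mc + 1)
  structure(list(D = D, p = p, n = n, n_mc = as.integer(n_mc),
                 seed = as.integer(seed)),
            class = "dip_test")
}

#' @export
print.dip_test <- function(x, ...) {
  cat(sprintf("Hartigan dip test: D = %.4g, p = %.4g (n = %d, %d MC replicates)\n",
              x$D, x$p, x$n, x$n_mc))
  invisible(x)
}

# Exact Gaussian-kernel density on a grid (outer sum, chunked); avoids
# the binning of stats::density so shallow near-critical modes are
# resolved exactly.
kde_grid <- function(x, h, grid) {
  n <- length(x)
  out <- numeric(length(grid))
  blocks <- split(seq_len(n), ceiling(seq_len(n) / 512))
  for (idx in blocks)
    out <- out + colSums(stats::dnorm(outer(x[idx], grid, `-`) / h))
  out / (n * h)
}

# Number of strict local maxima of the Gaussian KDE at bandwidth h.
kde_mode_count <- function(x, h, n_grid = 512L) {
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = n_grid)
  y <- kde_grid(x, h, grid)
  d <- diff(y)
  s <- sign(d)
  s <- s[s != 0]
  if (!length(s)) return(1L)             # flat: single repeated value
  sum(s[-1] < s[-length(s)])             # +1 -> -1 transitions
}

#' Count kernel-density modes
#'
#' Strict local maxima of a Gaussian kernel density estimate on a
#' 512-point grid spanning the data range plus/minus three bandwidths.
#'
#' @param x Numeric sample (n >= 2).
#' @param bandwidth Kernel standard deviation; default Silverman's
#'   rule-of-thumb ([stats::bw.nrd0()]).
#' @return Integer mode count (>= 1).
#' @examples
#' count_modes(c(-1, 1), bandwidth = 0.3)  # 2
#' count_modes(c(-1, 1), bandwidth = 2)    # 1
#' @export
count_modes <- function(x, bandwidth = NULL) {
  if (length(x) < 2) stop_invalid("count_modes() needs n >= 2")
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(x)
  if (bandwidth <= 0) stop_invalid("'bandwidth' must be positive")
  max(1L, kde_mode_count(x, bandwidth))
}

# Smallest bandwidth at which the KDE has <= k modes (mode count is
# nonincreasing in h for the Gaussian kernel), by bisection.
critical_bandwidth <- function(x, k, tol = 1e-4 * stats::sd(x),
                               n_grid = 1024L) {
  s <- stats::sd(x)
  if (s == 0) stop_invalid("degenerate sample: zero variance")
  hi <- 2 * s
  while (kde_mode_count(x, hi, n_grid) > k) hi <- hi * 2
  lo <- hi / 2
  while (kde_mode_count(x, lo, n_grid) <= k && lo > 1e-8 * s) lo <- lo / 2
  if (kde_mode_count(x, lo, n_grid) <= k) return(lo)  # <= k modes at any h
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (kde_mode_count(x, mid, n_grid) <= k) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Silverman's critical-bandwidth test
#'
#' Tests the null of at most `k_null` modes.  The statistic is the
#' critical bandwidth `h_crit`: the smallest Gaussian-kernel bandwidth
#' at which the KDE of the sample has `<= k_null` modes (bisection to
#' `1e-4 * sd(x)`).  The p-value is the smoothed-bootstrap fraction of
#' resamples -- drawn at `h_crit` with variance rescaling -- whose KDE
#' at `h_crit` has more than `k_null` modes.  (No Hall-York
#' calibration; the test is known to be mildly anti-conservative.)
#'
#' @param x Numeric sample (n >= 10).
#' @param k_null Null number of modes (>= 1).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return A list of class `"silverman_test"`: `k_null`, `h_crit`, `p`,
#'   `n_boot`, `seed`.
#' @export
silverman_test <- function(x, k_null = 1L, n_boot = 500L, seed = 1L) {
  if (length(x) < 10) stop_invalid("silverman_test() needs n >= 10")
  if (anyNA(x) || any(!is.finite(x))) stop_invalid("non-finite values")
  n <- length(x)
  h <- critical_bandwidth(x, k_null)
  v <- stats::var(x)
  xbar <- mean(x)
  shrink <- 1 / sqrt(1 + h^2 / v)
  exceed <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    xs <- x[sample.int(n, n, replace = TRUE)]
    y <- xbar + shrink * (xs - xbar + h * stats::rnorm(n))
    kde_mode_count(y, h, 1024L) > k_null
  }, NA))
  structure(list(k_null = as.integer(k_null), h_crit = h,
                 p = mean(exceed), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "silverman_test")
}

#' @export
print.silverman_test <- function(x, ...) {
  cat(sprintf("Silverman test (null: <= %d mode%s): h_crit = %.4g, p = %.4g (%d bootstrap resamples)\n",
              x$k_null, if (x$k_null > 1) "s" else "", x$h_crit, x$p, x$n_boot))
  invisible(x)
}

#' Stepwise mode search with the Silverman test
#'
#' Runs [silverman_test()] for `k = 1, 2, 3, ...` until the null of at
#' most `k` modes is first not rejected at `level`, mirroring the usual
#' stepwise reading of the critical-bandwidth ladder.
#'
#' @inheritParams silverman_test
#' @param level Rejection level (default 0.05).
#' @param k_max Largest null entertained.
#' @return A list of class `"silverman_ladder"`: `table` (one row per
#'   k) and `k_selected` (first non-rejected k, NA if none).
#' @export
silverman_ladder <- function(x, level = 0.05, k_max = 6L, n_boot = 500L,
                             seed = 1L) {
  rows <- list()
  k_sel <- NA_integer_
  for (k in seq_len(k_max)) {
    st <- silverman_test(x, k_null = k, n_boot = n_boot, seed = seed + k)
    rows[[k]] <- data.frame(k_null = k, h_crit = st$h_crit, p = st$p)
    if (st$p > level) { k_sel <- k; break }
  }
  structure(list(table = do.call(rbind, rows), k_selected = k_sel,
                 level = level),
            class = "silverman_ladder")
}

#' @export
print.silverman_ladder <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("First non-rejected null at level %.2g: %s modes\n",
              x$level, x$k_selected))
  invisible(x)
}

#' Simplified SiZer map
#'
#' For a grid of locations and log-spaced bandwidths, estimates the
#' derivative of the Gaussian KDE and classifies each (location,
#' bandwidth) cell by its pointwise normal confidence interval:
#' `"increasing"` (CI above 0), `"decreasing"` (CI below 0), `"zero"`
#' (CI straddles 0), or `"insufficient-data"` where the effective local
#' sample size `sum_i K_h(x - X_i)/K_h(0)` is below 5.
#'
#' @param x Numeric sample (n >= 20).
#' @param n_loc Number of locations (over the data range).
#' @param n_bw Number of bandwidths, log-spaced over
#'   `[bw.nrd0(x)/4, range(x)/2]` by default.
#' @param level CI level parameter (default 0.05 for 95% intervals).
#' @param bw_limits Optional length-2 bandwidth range.
#' @return A list of class `"sizer_map"`: `x` (locations), `h`
#'   (bandwidths), `class` (n_bw x n_loc character matrix), `deriv`,
#'   `se` (matching matrices).
#' @export
sizer_map <- function(x, n_loc = 101L, n_bw = 21L, level = 0.05,
                      bw_limits = NULL) {
  if (length(x) < 20) stop_invalid("sizer_map() needs n >= 20")
  n <- length(x)
  if (is.null(bw_limits))
    bw_limits <- c(stats::bw.nrd0(x) / 4, diff(range(x)) / 2)
  h_grid <- exp(seq(log(bw_limits[1]), log(bw_limits[2]), length.out = n_bw))
  loc <- seq(min(x), max(x), length.out = n_loc)
  zq <- stats::qnorm(1 - level / 2)
  cls <- matrix("zero", n_bw, n_loc)
  est <- se <- matrix(NA_real_, n_bw, n_loc)
  for (b in seq_len(n_bw)) {
    h <- h_grid[b]
    U <- outer(loc, x, `-`) / h                    # n_loc x n
    W <- stats::dnorm(U)
    D <- -U * W / h^2                              # d/dx of the scaled kernel
    m <- rowMeans(D)
    s <- sqrt(pmax(0, rowMeans(D^2) - m^2) / n)
    ess <- rowSums(W) / stats::dnorm(0)
    lo <- m - zq * s
    hi <- m + zq * s
    row_cls <- ifelse(lo > 0, "increasing",
                      ifelse(hi < 0, "decreasing", "zero"))
    row_cls[ess < 5] <- "insufficient-data"
    cls[b, ] <- row_cls
    est[b, ] <- m
    se[b, ] <- s
  }
  structure(list(x = loc, h = h_grid, class = cls, deriv = est, se = se),
            class = "sizer_map")
}

#' @export
print.sizer_map <- function(x, ...) {
  tab <- table(factor(x$class,
                      levels = c("increasing", "decreasing", "zero",
                                 "insufficient-data")))
  cat(sprintf("SiZer map: %d locations x %d bandwidths\n",
              length(x$x), length(x$h)))
  print(tab)
  invisible(x)
}
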
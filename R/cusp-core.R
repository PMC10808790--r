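# Deterministic mathematics of the cusp stationary density:
# kernel, normalization, equilibria, bifurcation-set classification,
# and state-prediction conventions.

#' Log-density kernel of the cusp stationary density
#'
#' Evaluates `U(y; alpha, beta) = alpha*y + (1/2)*beta*y^2 - (1/4)*y^4`,
#' the exponent of Cobb's stationary density for the stochastic cusp
#' process.  The density itself is `exp(U)/psi(alpha, beta)` (see
#' [cusp_psi()]).  `U` is used directly as the log-density exponent
#' (the "physics" potential is `-U`).
#'
#' @param y Numeric vector of state values.
#' @param alpha Numeric vector, asymmetry control value(s).
#' @param beta Numeric vector, bifurcation control value(s).
#' @return Numeric vector of kernel values (usual recycling rules).
#' @examples
#' cusp_kernel(1, alpha = 1, beta = 2)  # 1.75
#' @export
cusp_kernel <- function(y, alpha, beta) {
  if (!is.numeric(y) || !is.numeric(alpha) || !is.numeric(beta))
    stop_invalid("'y', 'alpha' and 'beta' must be numeric")
  if (anyNA(y) || anyNA(alpha) || anyNA(beta) ||
      any(!is.finite(y)) || any(!is.finite(alpha)) || any(!is.finite(beta)))
    stop_invalid("non-finite input to cusp_kernel()")
  alpha * y + 0.5 * beta * y^2 - 0.25 * y^4
}

#' Discriminant of the cusp bifurcation set
#'
#' `delta = 27*alpha^2 - 4*beta^3`.  Negative values place the control
#' point inside the bifurcation set (two stable regimes, bimodal
#' density), positive values outside (unimodal), zero on the boundary.
#'
#' @inheritParams cusp_kernel
#' @return Numeric vector of discriminant values.
#' @export
cusp_delta <- function(alpha, beta) {
  27 * alpha^2 - 4 * beta^3
}

#' Classify control points against the bifurcation set
#'
#' @inheritParams cusp_kernel
#' @param tol Relative tolerance for calling the discriminant zero.
#' @return Character vector with values `"bimodal"`, `"unimodal"` or
#'   `"boundary"`.
#' @export
cusp_classify <- function(alpha, beta, tol = 1e-10) {
  d <- cusp_delta(alpha, beta)
  scale <- pmax(1, 27 * alpha^2, 4 * abs(beta)^3)
  out <- ifelse(d < -tol * scale, "bimodal",
                ifelse(d > tol * scale, "unimodal", "boundary"))
  as.character(out)
}

# Stable closed-form roots of y^3 - beta*y - alpha = 0 (equilibria of U),
# vectorized over (alpha, beta).  Returns an n x 3 matrix, NA-padded,
# roots sorted increasing; two Newton polish steps remove the branch
# ambiguity of the trigonometric/Cardano formulas.
cusp_roots_mat <- function(alpha, beta) {
  n <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, n)
  beta <- rep_len(beta, n)
  p <- -beta
  q <- -alpha
  disc <- -4 * p^3 - 27 * q^2          # = 4*beta^3 - 27*alpha^2 = -cusp_delta
  scale <- pmax(1, abs(p)^3, q^2)
  three <- disc > 1e-12 * scale        # strictly inside the bifurcation set
  out <- matrix(NA_real_, n, 3)
  if (any(three)) {
    pp <- p[three]; qq <- q[three]
    m <- 2 * sqrt(-pp / 3)
    arg <- pmin(1, pmax(-1, 3 * qq / (2 * pp) * sqrt(-3 / pp)))
    th <- acos(arg)
    r <- cbind(m * cos(th / 3),
               m * cos((th - 2 * pi) / 3),
               m * cos((th - 4 * pi) / 3))
    out[three, ] <- t(apply(r, 1, sort))
  }
  if (any(!three)) {
    pp <- p[!three]; qq <- q[!three]
    s2 <- qq^2 / 4 + pp^3 / 27
    s2[s2 < 0] <- 0                    # boundary: repeated roots collapse
    s <- sqrt(s2)
    cbrt <- function(v) sign(v) * abs(v)^(1 / 3)
    out[!three, 1] <- cbrt(-qq / 2 + s) + cbrt(-qq / 2 - s)
  }
  # Newton polish: y <- y - f/f' with f = y^3 - beta*y - alpha
  for (i in 1:2) {
    f <- out^3 - beta * out - alpha
    fp <- 3 * out^2 - beta
    step <- ifelse(is.na(out) | abs(fp) < 1e-12, 0, f / fp)
    out <- out - step
  }
  out
}

#' Equilibria of the cusp potential at a control point
#'
#' Solves `alpha + beta*y - y^3 = 0` (the stationary points of the
#' kernel `U`) via the trigonometric/Cardano closed form with Newton
#' polishing, labels each root as a stable mode (`U'' < 0`) or unstable
#' antimode, and classifies the control point against the bifurcation
#' set.  Exactly on the boundary repeated roots are deduplicated at
#' tolerance `1e-8` and the point is labeled `"boundary"` (treated as
#' unimodal for prediction).
#'
#' @param alpha,beta Scalar control values.
#' @return A list of class `"cusp_equilibria"` with elements `roots`
#'   (increasing), `stability` (`"stable"`/`"antimode"`), `region`, and
#'   `delta`.
#' @examples
#' cusp_equilibria(0, 1)  # roots -1, 0, 1; outer stable, middle antimode
#' @export
cusp_equilibria <- function(alpha, beta) {
  stopifnot(length(alpha) == 1, length(beta) == 1)
  if (!is.finite(alpha) || !is.finite(beta))
    stop_invalid("non-finite control point")
  region <- cusp_classify(alpha, beta)
  r <- cusp_roots_mat(alpha, beta)[1, ]
  r <- sort(r[!is.na(r)])
  if (length(r) > 1)                    # deduplicate repeated roots
    r <- r[c(TRUE, diff(r) > 1e-8)]
  stab <- ifelse(beta - 3 * r^2 < 0, "stable", "antimode")
  # a lone inflection-type root (boundary case) still attracts mass
  if (length(r) == 1) stab <- "stable"
  structure(list(roots = r, stability = stab, region = region,
                 delta = cusp_delta(alpha, beta)),
            class = "cusp_equilibria")
}

#' @export
print.cusp_equilibria <- function(x, ...) {
  cat("Cusp equilibria (", x$region, ", delta = ",
      format(x$delta, digits = 6), ")\n", sep = "")
  print(data.frame(root = x$roots, stability = x$stability))
  invisible(x)
}

# Global maximizer of U(.; alpha, beta): the stable root with the
# largest kernel value.  Returns c(mode, Umax).
cusp_mode <- function(alpha, beta) {
  eq <- cusp_equilibria(alpha, beta)
  r <- eq$roots[eq$stability == "stable"]
  u <- cusp_kernel(r, alpha, beta)
  i <- which.max(u)
  c(mode = r[i], umax = u[i])
}

# Integration window [m - R, m + R] around the global mode m, with R
# grown until the kernel has fallen `drop` log-units below its maximum
# at both ends (default drop = 40, far below double precision).
cusp_support <- function(alpha, beta, drop = 40) {
  mu <- cusp_mode(alpha, beta)
  R <- 2
  repeat {
    lo <- mu[["mode"]] - R
    hi <- mu[["mode"]] + R
    if (cusp_kernel(lo, alpha, beta) < mu[["umax"]] - drop &&
        cusp_kernel(hi, alpha, beta) < mu[["umax"]] - drop) break
    R <- R * 1.5
    if (R > 1e6) stop_numeric("could not bracket the cusp density support")
  }
  c(lo, hi)
}

#' Normalizing constant of the cusp stationary density
#'
#' Computes `psi(alpha, beta) = integral exp(U(y; alpha, beta)) dy` over
#' the real line by adaptive quadrature on a window around the global
#' mode chosen so the kernel falls 40 log-units below its maximum.  The
#' integrand is rescaled by `exp(-Umax)` internally so the quadrature is
#' well conditioned for any finite controls.
#'
#' @param alpha,beta Scalar control values.
#' @param rel_tol Relative tolerance of the quadrature, in `(0, 1e-3]`.
#' @return The positive scalar `psi`.
#' @examples
#' cusp_psi(0, 0)  # 2^(-1/2) * gamma(1/4) ~= 2.5637
#' @export
cusp_psi <- function(alpha, beta, rel_tol = 1e-8) {
  stopifnot(length(alpha) == 1, length(beta) == 1)
  if (!is.finite(alpha) || !is.finite(beta))
    stop_invalid("non-finite control point")
  if (!(rel_tol > 0 && rel_tol <= 1e-3))
    stop_invalid("'rel_tol' must be in (0, 1e-3]")
  mu <- cusp_mode(alpha, beta)
  win <- cusp_support(alpha, beta)
  res <- tryCatch(
    stats::integrate(function(y) exp(cusp_kernel(y, alpha, beta) - mu[["umax"]]),
                     win[1], win[2], rel.tol = rel_tol, abs.tol = 0,
                     subdivisions = 500L),
    error = function(e) e)
  if (inherits(res, "error") || res$message != "OK")
    stop_numeric(paste0("quadrature for psi(", alpha, ", ", beta, ") failed: ",
                        conditionMessage(if (inherits(res, "error")) res else
                          simpleError(res$message))))
  res$value * exp(mu[["umax"]])
}

#' Cusp state density
#'
#' Normalized stationary density `exp(U)/psi` at state values `y`.
#'
#' @inheritParams cusp_kernel
#' @param alpha,beta Scalar control values.
#' @return Numeric vector of density values.
#' @export
cusp_density <- function(y, alpha, beta) {
  exp(cusp_kernel(y, alpha, beta)) / cusp_psi(alpha, beta)
}

#' Predict the state at a control point
#'
#' Three standard fitted-value conventions for cusp models:
#' * `"delay"`: the stable equilibrium nearest `previous_state`
#'   (hysteresis-respecting).
#' * `"maxwell"`: the global maximizer of the stationary density.
#' * `"mean"`: the mean of the stationary density, by quadrature.
#'
#' Under the Maxwell convention an exact density tie between the two
#' stable regimes (alpha = 0, beta > 0) returns the positive root and
#' flags the result with `attr(., "ambiguous")`.
#'
#' @param alpha,beta Scalar control values.
#' @param convention One of `"delay"`, `"maxwell"`, `"mean"`.
#' @param previous_state Previous system state; required for `"delay"`.
#' @return Predicted state (scalar), possibly with attribute `ambiguous`.
#' @export
cusp_predict <- function(alpha, beta,
                         convention = c("delay", "maxwell", "mean"),
                         previous_state = NULL) {
  convention <- match.arg(convention)
  if (!is.finite(alpha) || !is.finite(beta))
    stop_invalid("non-finite control point")
  eq <- cusp_equilibria(alpha, beta)
  stable <- eq$roots[eq$stability == "stable"]
  switch(convention,
    delay = {
      if (is.null(previous_state))
        stop_invalid("the delay convention requires 'previous_state'")
      stable[which.min(abs(stable - previous_state))]
    },
    maxwell = {
      u <- cusp_kernel(stable, alpha, beta)
      if (length(stable) > 1 && diff(range(u)) < 1e-12) {
        out <- max(stable)
        attr(out, "ambiguous") <- TRUE
        out
      } else stable[which.max(u)]
    },
    mean = {
      psi <- cusp_psi(alpha, beta)
      win <- cusp_support(alpha, beta)
      umax <- cusp_mode(alpha, beta)[["umax"]]
      res <- stats::integrate(function(y)
        y * exp(cusp_kernel(y, alpha, beta) - umax),
        win[1], win[2], rel.tol = 1e-8, abs.tol = 1e-12, subdivisions = 500L)
      res$value * exp(umax) / psi
    })
}
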
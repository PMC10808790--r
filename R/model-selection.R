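# Information criteria, likelihood-ratio contrast, pseudo-R2 and fit
# diagnostics assembled into a three-model comparison table.

#' Information criteria from a log-likelihood
#'
#' `AIC = 2k - 2*loglik`, `AICc = AIC + 2k(k+1)/(n-k-1)`,
#' `BIC = k*log(n) - 2*loglik`.  `k` is an explicit input so any
#' parameter-counting convention can be replayed.
#'
#' @param loglik Log-likelihood at the optimum.
#' @param k Number of free parameters (>= 0).
#' @param n Number of observations (needed for AICc and BIC; `n > k + 1`
#'   for AICc).
#' @return A one-row data frame with `loglik`, `k`, `AIC`, `AICc`, `BIC`.
#' @examples
#' information_criteria(-3486.770, 7, 2420)
#' @export
information_criteria <- function(loglik, k, n) {
  stopifnot(is.finite(loglik), k >= 0, n >= 1)
  if (n <= k + 1)
    stop_invalid("AICc requires n > k + 1")
  aic <- 2 * k - 2 * loglik
  data.frame(loglik = loglik, k = as.integer(k),
             AIC = aic,
             AICc = aic + 2 * k * (k + 1) / (n - k - 1),
             BIC = k * log(n) - 2 * loglik)
}

#' Likelihood-ratio contrast between nested fits
#'
#' `chi2 = 2*(loglik_complex - loglik_simple)` on
#' `df = k_complex - k_simple` degrees of freedom, with the p-value from
#' the upper chi-square tail.  Inputs may be `fit_result` objects or
#' plain lists with `loglik` and `k` (so printed table values can be
#' replayed).  A complex fit with the lower likelihood yields `chi2 = 0`
#' with a warning (misfit indicator).
#'
#' @param fit_simple,fit_complex Fits (or lists) with `$loglik`, `$k`.
#' @return A list of class `"lr_test"`: `chi2`, `df`, `p`.
#' @examples
#' likelihood_ratio_test(list(loglik = -5836.003, k = 4),
#'                       list(loglik = -3486.770, k = 7))
#' @export
likelihood_ratio_test <- function(fit_simple, fit_complex) {
  ls <- fit_simple$loglik; lc <- fit_complex$loglik
  ks <- fit_simple$k; kc <- fit_complex$k
  stopifnot(is.finite(ls), is.finite(lc))
  if (!(ks < kc))
    stop_invalid("fit_simple must have fewer parameters than fit_complex")
  chi2 <- 2 * (lc - ls)
  if (chi2 < 0) {
    warning("complex model has lower log-likelihood than the simple one; ",
            "chi2 clamped at 0 (misfit indicator)", call. = FALSE)
    chi2 <- 0
  }
  df <- as.integer(kc - ks)
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("Likelihood-ratio contrast: chi2(%d) = %.3f, p = %.3g\n",
              x$df, x$chi2, x$p))
  invisible(x)
}

#' Diagnostics for a fitted cusp model
#'
#' Fitted values follow the delay convention with the observed rescaled
#' state as the previous position: for every observation the fitted
#' state is the stable equilibrium of `U(.; alpha_i, beta_i)` nearest
#' `z_i = w0 + w1*Y_i`.  Residuals are `z - fitted`;
#' `pseudo_R2 = 1 - Var(residual)/Var(z)`.  Each observation is also
#' classified against the bifurcation set `27*alpha^2 < 4*beta^3`.
#'
#' @param fit A converged `cusp_fit`.
#' @param data The study table the model was fitted to.
#' @return A list of class `"cusp_diagnostics"`: `fitted`, `residuals`
#'   (both in rescaled state units), `pseudo_r2`, `region` (per row),
#'   `n_bifurcation`, and `cor_residual_fitted`.
#' @export
fit_diagnostics <- function(fit, data) {
  stopifnot(inherits(fit, "cusp_fit"))
  if (!isTRUE(fit$converged))
    warning("diagnostics computed from a non-converged fit", call. = FALSE)
  data <- as_study_table(data)
  v <- study_columns(data)
  e <- fit$estimates
  alpha <- e[["a0"]] + e[["a1"]] * v$asymmetry
  beta <- e[["b0"]] + e[["b1"]] * v$bifurcation
  z <- e[["w0"]] + e[["w1"]] * v$state
  roots <- cusp_roots_mat(alpha, beta)
  # stable roots only: where three roots exist the middle is the antimode
  roots[, 2][!is.na(roots[, 3])] <- NA
  dist <- abs(roots - z)
  pick <- max.col(-ifelse(is.na(dist), Inf, dist), ties.method = "first")
  fitted <- roots[cbind(seq_along(z), pick)]
  res <- z - fitted
  region <- cusp_classify(alpha, beta)
  pseudo_r2 <- 1 - stats::var(res) / stats::var(z)
  structure(list(fitted = fitted, residuals = res, pseudo_r2 = pseudo_r2,
                 region = region, n_bifurcation = sum(region == "bimodal"),
                 cor_residual_fitted = suppressWarnings(
                   stats::cor(res, fitted))),
            class = "cusp_diagnostics")
}

#' @export
print.cusp_diagnostics <- function(x, ...) {
  cat(sprintf("Cusp diagnostics: pseudo-R2 = %.3f, %d of %d observations inside the bifurcation set\n",
              x$pseudo_r2, x$n_bifurcation, length(x$fitted)))
  cat(sprintf("cor(residual, fitted) = %.3f\n", x$cor_residual_fitted))
  invisible(x)
}

#' Compare the linear, logistic and cusp models on one study table
#'
#' Fits all three models (shared seed and multi-start policy), builds a
#' comparison table of log-likelihoods and information criteria, and
#' contrasts the linear against the cusp model with a likelihood-ratio
#' test.  Internal parameter counts are (4, 5, 6); `k_override` replays
#' the arithmetic under any other counting convention.
#'
#' @inheritParams fit_cusp
#' @param k_override Optional named list/vector (names among `linear`,
#'   `logistic`, `cusp`) of parameter counts to use in the criteria and
#'   the LR degrees of freedom instead of the internal ones.
#' @return A list of class `"cusp_model_comparison"`: `table` (one row
#'   per model, with `best` flags per criterion), `lr` (linear vs cusp),
#'   and the three fits.
#' @export
compare_models <- function(data, n_starts = 10L, seed = 1L, n_grid = 401L,
                           k_override = NULL) {
  data <- as_study_table(data)
  fits <- list(linear = fit_linear(data),
               logistic = fit_logistic(data, n_starts = n_starts, seed = seed),
               cusp = fit_cusp(data, n_starts = n_starts, seed = seed,
                               n_grid = n_grid))
  n <- fits$linear$n
  rows <- lapply(names(fits), function(m) {
    k <- fits[[m]]$k
    k_used <- if (!is.null(k_override) && m %in% names(k_override))
      as.integer(k_override[[m]]) else k
    cbind(data.frame(model = m, k_internal = k),
          information_criteria(fits[[m]]$loglik, k_used, n))
  })
  tab <- do.call(rbind, rows)
  tab$best_AIC <- tab$AIC == min(tab$AIC)
  tab$best_AICc <- tab$AICc == min(tab$AICc)
  tab$best_BIC <- tab$BIC == min(tab$BIC)
  lr <- likelihood_ratio_test(
    list(loglik = tab$loglik[tab$model == "linear"],
         k = tab$k[tab$model == "linear"]),
    list(loglik = tab$loglik[tab$model == "cusp"],
         k = tab$k[tab$model == "cusp"]))
  structure(list(table = tab, lr = lr, fits = fits, n = n),
            class = "cusp_model_comparison")
}

#' @export
print.cusp_model_comparison <- function(x, ...) {
  cat("Model comparison (n =", x$n, ")\n")
  print(x$table[, c("model", "loglik", "k", "AIC", "AICc", "BIC")],
        digits = 8, row.names = FALSE)
  print(x$lr)
  invisible(x)
}
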
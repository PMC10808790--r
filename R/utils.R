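# Internal helpers: classed conditions, seed scoping, quadrature weights.

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("cuspfit_invalid_error", "cuspfit_error")))
}

stop_numeric <- function(msg) {
  stop(errorCondition(msg, class = c("cuspfit_numeric_error", "cuspfit_error")))
}

stop_schema <- function(msg) {
  stop(errorCondition(msg, class = c("cuspfit_schema_error", "cuspfit_error")))
}

stop_identifiability <- function(msg) {
  stop(errorCondition(msg,
    class = c("cuspfit_identifiability_error", "cuspfit_error")))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Row maxima of a numeric matrix without copying (via max.col).
row_max <- function(M) {
  M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
}
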
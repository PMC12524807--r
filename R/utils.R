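# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so that seeded package internals
#' never perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_cf <- function(..., class = "coxformer_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_cf(name, " must be a single finite number", class = "coxformer_config_error")
  }
  if (integer && x != round(x)) {
    stop_cf(name, " must be an integer", class = "coxformer_config_error")
  }
  if (x < lower || x > upper || (strict_lower && x <= lower)) {
    stop_cf(name, " out of range [", lower, ", ", upper, "]",
            class = "coxformer_config_error")
  }
  invisible(x)
}
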
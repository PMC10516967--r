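#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the previous state so seeded package internals never
#' perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

assert_scalar_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != floor(x))
    stop_field(field, "must be a single positive integer")
  invisible(as.integer(x))
}

assert_prob <- function(x, field, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (open_upper && x >= 1) || (!open_upper && x > 1))
    stop_field(field, if (open_upper) "must lie in [0, 1)" else "must lie in [0, 1]")
  invisible(as.numeric(x))
}
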
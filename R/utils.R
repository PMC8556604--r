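# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so generators are reproducible without clobbering user randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Relative Frobenius error between two matrices/vectors.
rel_error <- function(est, ref) {
  d <- sqrt(sum((est - ref)^2))
  s <- sqrt(sum(ref^2))
  if (s == 0) d else d / s
}

# stop() with a classed condition so callers/tests can match on error type.
abort <- function(msg, class) {
  stop(structure(class = c(class, "icaclean_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
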
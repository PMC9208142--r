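#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so that seeded operations inside the
#' package never disturb a user's simulation stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
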
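`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their arguments.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## sub-seed derivation that stays inside 32-bit integer range
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) * 7919L
}

vec3 <- function(x, what = "value") {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- rep(x, 3L)
  if (length(x) != 3L) stop("`", what, "` must have length 1 or 3")
  x
}
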
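`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for the percentage tables in QSPR reports (base `round()`
#' uses banker's rounding).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Express a proportion as a percentage
#'
#' @param x proportion (or correlation in `[-1, 1]`).
#' @param digits decimal places, half-up.
#' @return `x * 100` rounded half-up.
#' @export
as_percent <- function(x, digits = 1) round_half_up(100 * x, digits)

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_ <- function(...) stop(..., call. = FALSE)
warn_ <- function(...) warning(..., call. = FALSE)
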
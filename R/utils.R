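# Shared internal helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; cohort percentages are reported
#' rounded half-up to match clinical reporting conventions.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() with a consistent call-free style
abort <- function(...) stop(..., call. = FALSE)

# Evaluate `expr` under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
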
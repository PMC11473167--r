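#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding, as used when reporting category percentages to one
#' decimal. Base R's `round()` rounds half to even, which gives e.g.
#' `round(0.5) == 0`; reported percentages instead carry halves away from
#' zero.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return `x` rounded half-away-from-zero to `digits` decimals.
#' @examples
#' round_half_up(c(5.85, 20.05), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Derive a reproducible sub-seed from one global seed so that independent
# generators (atlas, gene models, counts, reads) can be re-run in isolation.
# Kept well below 2^31 - 1.
substream_seed <- function(seed, offset) {
  (abs(as.integer(seed)) + 97L * as.integer(offset)) %% 2147483629L
}

# Evaluate `expr` with a locally fixed RNG state, restoring the caller's
# stream afterwards. Used where a downstream library draws random numbers
# internally (multivariate-t quadrature) and the pipeline must stay
# bit-reproducible.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
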
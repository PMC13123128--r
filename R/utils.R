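# internal numerics shared across the package

# log(1 + exp(x)) without overflow; piecewise thresholds follow the usual
# double-precision analysis (Maechler-style)
log1pexp <- function(x) {
  out <- numeric(length(x))
  hi <- x > 33.3
  mid <- !hi & x > 18
  lo <- !hi & !mid & x > -37
  tiny <- !hi & !mid & !lo
  out[hi] <- x[hi]
  out[mid] <- x[mid] + exp(-x[mid])
  out[lo] <- log1p(exp(x[lo]))
  out[tiny] <- exp(x[tiny])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# local RNG scope: run code with a given seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

stopifnot_finite <- function(x, what) {
  if (any(!is.finite(x))) stop(sprintf("non-finite %s", what), call. = FALSE)
  invisible(x)
}
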
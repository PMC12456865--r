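#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.25 -> 0.3` at one decimal), the
#' convention used for all one-decimal values in reports. Base R's `round()`
#' rounds half to even, which disagrees on exactly these ties.
#'
#' @param x numeric vector (non-negative values expected in reports)
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # tiny epsilon guards ties that land an ulp below .5 after the multiply
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible child seed below 2^31 from (seed, index)
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
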
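#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used when printing scores and report
#' values. Base [round()] rounds half to even, which would turn 2.555 into
#' 2.56 or 2.54 depending on binary representation; score reporting here
#' always rounds .5 upward in magnitude.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(1.665, 2)
#' round_half_up(2.555, 2)
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded sessions do not disturb the ambient stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar test helpers for argument validation
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}
is_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
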
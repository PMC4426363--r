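#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used when
#' printed percentages are reproduced from raw count pairs. (Base `round()`
#' rounds half to even, which turns e.g. 56.25 into 56.2 rather than 56.3.)
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_away(56.25, 1)  # 56.3, where round() gives 56.2
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## strict scalar checks used by the user-facing constructors
is_count1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
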
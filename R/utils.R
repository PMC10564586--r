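#' Round half away from zero
#'
#' Commercial rounding as used in the published tables: ties go away from
#' zero (2.5 -> 3, -2.5 -> -3), unlike [base::round()]'s round-half-even.
#' All internal computation is unrounded; this is applied only when values
#' are displayed or when a table convention explicitly works on rounded
#' values (the growth-delta rows).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_up(c(3.55, -3.55, 0.36764), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # nudge by a relative epsilon so values stored as 3.549999... round as 3.55
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)
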
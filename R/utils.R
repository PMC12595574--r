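#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero (2.5 -> 3, -2.5 -> -3),
#' unlike [round()] which rounds half to even. Used everywhere a value is
#' rounded for display or for integer rating scores, so results are
#' platform-stable.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places. Default 0.
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5), 0)  # 1, 2, -1
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Fixed-decimal formatting with half-away-from-zero ties (sprintf's %f
# inherits the C library's tie behavior, so round first).
format_fixed <- function(x, digits) {
  sprintf(paste0("%.", digits, "f"), round_half_away(x, digits))
}

# Numbers formatted so that read.csv round-trips them exactly.
format_full <- function(x) {
  sprintf("%.17g", x)
}
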
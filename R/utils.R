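#' Round half away from zero
#'
#' Commercial ("half away from zero") rounding, used when comparing computed
#' degree-of-saturation values against tabulated two-decimal figures. Base
#' [round()] rounds half to even, which would turn 0.875 into 0.88 here too,
#' but 0.885 into 0.88; this helper makes the convention explicit and stable.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_away(0.875, 2) # 0.88
#' round_half_away(0.625, 2) # 0.63
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Instrument wavelength grid
#'
#' The line-scan camera's spectral axis: 512 bands from 760 nm in 2.2 nm
#' steps (upper end 1884.2 nm).
#'
#' @param start first band center, nm.
#' @param step band interval, nm.
#' @param n number of bands.
#' @return numeric vector of band-center wavelengths in nm.
#' @export
instrument_wavelengths <- function(start = 760, step = 2.2, n = 512L) {
  start + step * (seq_len(n) - 1)
}
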
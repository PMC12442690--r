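#' @include AllClasses.R
NULL

# Gyromagnetic ratios relative to 1H. The 15N and 13C values are magnitudes:
# only |delta omega| enters the observables simulated here, so the sign of
# gamma(15N) is ignored.
.nucleus_table <- data.frame(
  name = c("1H", "15N", "13C"),
  gamma_rel = c(1.0, 0.10136767, 0.25144953),
  stringsAsFactors = FALSE)

#' Gyromagnetic ratio relative to 1H
#'
#' @param nucleus one of "1H", "15N", "13C".
#' @return dimensionless positive ratio; exactly 1 for 1H.
#' @export
gyromagneticRatio <- function(nucleus) {
  i <- match(nucleus, .nucleus_table$name)
  if (any(is.na(i))) stop("unknown nucleus: ", nucleus[is.na(i)][1])
  .nucleus_table$gamma_rel[i]
}

#' Larmor frequency of a nucleus at a field stated as 1H MHz
#'
#' @param nucleus nucleus label.
#' @param B0_MHz_1H spectrometer field expressed as the 1H resonance
#'   frequency in MHz (e.g. 700 for 16.4 T).
#' @return resonance frequency in MHz.
#' @examples
#' larmorMHz("15N", 700)  # ~70.96 MHz
#' @export
larmorMHz <- function(nucleus, B0_MHz_1H) {
  gyromagneticRatio(nucleus) * B0_MHz_1H
}

#' Convert a ppm difference to angular frequency
#'
#' Linear conversion: \code{domega = 2 * pi * larmor_MHz * dppm} rad/s
#' (larmor in MHz times ppm gives Hz).
#'
#' @param dppm chemical-shift difference in ppm.
#' @param nucleus nucleus label.
#' @param B0_MHz_1H field as 1H MHz.
#' @return angular frequency in rad/s.
#' @export
ppmToRadSec <- function(dppm, nucleus, B0_MHz_1H) {
  2 * pi * larmorMHz(nucleus, B0_MHz_1H) * dppm
}
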
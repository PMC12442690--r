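#' @include AllClasses.R
NULL

# Default 15N CEST acquisition grids, one per spectrometer field. Offsets,
# increments, B1 fields (15/60 Hz) and saturation times follow the
# acquisition settings for this study system.
.cest_grids <- list(
  "11.7" = list(B0 = 500, from = 100.78, to = 132.23, by = 0.79, Tex = 0.30),
  "16.4" = list(B0 = 700, from = 102.00, to = 132.00, by = 0.38, Tex = 0.40),
  "18.8" = list(B0 = 800, from = 100.76, to = 132.36, by = 0.49, Tex = 0.35),
  "22.3" = list(B0 = 950, from = 102.00, to = 132.00, by = 0.38, Tex = 0.40))

#' Default 15N CEST scheme for a given field
#'
#' Returns the standard saturation grid used throughout the package: at
#' 16.4 T, 80 offsets from 102 to 132 ppm in 0.38 ppm increments with
#' Tex = 0.4 s; analogous grids at 11.7, 18.8 and 22.3 T.
#'
#' @param field_T static field in Tesla (11.7, 16.4, 18.8 or 22.3).
#' @param B1_Hz saturation field, typically 15 or 60 Hz.
#' @return a [CestScheme-class].
#' @examples
#' length(defaultCestScheme(16.4, 15)@offsets_ppm)  # 80
#' @export
defaultCestScheme <- function(field_T = 16.4, B1_Hz = 15) {
  g <- .cest_grids[[sprintf("%.1f", field_T)]]
  if (is.null(g)) stop("no default grid for field ", field_T, " T")
  npts <- round((g$to - g$from) / g$by) + 1
  cestScheme(B0_MHz_1H = g$B0, nucleus = "15N", B1_Hz = B1_Hz,
             Tex_s = g$Tex, offsets_ppm = g$from + g$by * (seq_len(npts) - 1))
}

#' Default amide 1H CEST scheme
#'
#' Amide-proton saturation grid at 22.3 T (950 MHz): 5.5 to 10.6 ppm in
#' 0.06 ppm steps, B1 = 60 Hz, Tex = 0.3 s.
#'
#' @param B1_Hz saturation field.
#' @return a [CestScheme-class].
#' @export
defaultAmideCestScheme <- function(B1_Hz = 60) {
  cestScheme(B0_MHz_1H = 950, nucleus = "1H", B1_Hz = B1_Hz, Tex_s = 0.3,
             offsets_ppm = seq(5.5, 10.6, by = 0.06))
}

#' Default 15N CPMG scheme
#'
#' Constant-time CPMG with Tcp = 40 ms and 20 pulsing frequencies between 25
#' and 1000 Hz, every one an integer number of echoes (nu = n/Tcp).
#'
#' @param B0_MHz_1H field as 1H MHz (default 800, i.e. 18.8 T).
#' @return a [CpmgScheme-class].
#' @export
defaultCpmgScheme <- function(B0_MHz_1H = 800) {
  n <- c(1:14, 16, 18, 20, 25, 32, 40)
  cpmgScheme(B0_MHz_1H = B0_MHz_1H, nucleus = "15N", Tcp_s = 0.040,
             nu_cpmg_Hz = n / 0.040)
}
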
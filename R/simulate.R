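#' @include AllClasses.R rate-matrix.R nucleus.R
NULL

#' Simulate a CEST profile by Bloch-McConnell evolution
#'
#' For each saturation offset, the full magnetization vector (Mx, My, Mz per
#' state, plus one constant element carrying the R1-driven return to
#' equilibrium) is propagated for the saturation time \code{Tex_s} with a
#' matrix-exponential propagator, exact for the piecewise-constant
#' Hamiltonian. The reported intensity ratio is the longitudinal magnetization
#' of the observed state divided by its value at \code{Tex = 0} (the
#' reference-spectrum convention).
#'
#' @param model an [ExchangeModel-class]; \code{shift_ppm} must refer to the
#'   scheme's nucleus.
#' @param scheme a [CestScheme-class].
#' @param observe label of the observed (detected) state; default is the
#'   state with the largest population (ties broken by state order).
#' @return A [RelaxationProfile-class] with \code{x} = offset (ppm) and
#'   \code{y} = I/I0.
#' @seealso [simulateCpmg()], [generateCestDataset()]
#' @export
simulateCest <- function(model, scheme, observe = NULL) {
  stopifnot(is(model, "ExchangeModel"), is(scheme, "CestScheme"))
  validObject(model); validObject(scheme)
  if (any(is.na(model@states$shift_ppm)))
    stop("model is missing chemical shifts for nucleus ", scheme@nucleus)
  st <- model@states
  obs <- if (is.null(observe)) st$label[which.max(st$population)] else observe
  oi <- match(obs, st$label)
  if (is.na(oi)) stop("unknown observed state: ", obs)
  ratios <- bm_cest(st$population, st$R1, st$R2, st$shift_ppm,
                    larmorMHz(scheme@nucleus, scheme@B0_MHz_1H),
                    scheme@offsets_ppm, scheme@B1_Hz, scheme@Tex_s,
                    buildRateMatrix(model))
  relaxationProfile("cest", residue = "sim", nucleus = scheme@nucleus,
                    temperatureK = NA_real_, B0_MHz_1H = scheme@B0_MHz_1H,
                    meta = list(B1_Hz = scheme@B1_Hz, Tex_s = scheme@Tex_s,
                                observe = obs),
                    data = data.frame(x = scheme@offsets_ppm,
                                      y = ratios[oi, ], sigma = 1))
}

# All-states CEST ratios (S x n matrix); fitting-path workhorse that avoids
# re-propagating when both the N- and D-observed peaks are fitted.
cestRatios <- function(populations, R1, R2, shifts_ppm, nucleus, B0_MHz_1H,
                       offsets_ppm, B1_Hz, Tex_s, K) {
  bm_cest(populations, R1, R2, shifts_ppm, larmorMHz(nucleus, B0_MHz_1H),
          offsets_ppm, B1_Hz, Tex_s, K)
}

#' Simulate a constant-time CPMG relaxation-dispersion profile
#'
#' In-phase transverse magnetization (complex M+ per state) is propagated
#' through the echo train \code{[tau-180-tau]^(2n)} with ideal instantaneous
#' 180-degree pulses (complex conjugation), \code{tau = Tcp/(4n)},
#' \code{n = round(nu * Tcp)}. The effective relaxation rate is
#' \code{R2eff = -(1/Tcp) * log(|M_obs(Tcp)| / M_obs(0))}.
#'
#' @inheritParams simulateCest
#' @param scheme a [CpmgScheme-class].
#' @return A [RelaxationProfile-class] with \code{x} = nu_cpmg (Hz) and
#'   \code{y} = R2eff (s^-1).
#' @export
simulateCpmg <- function(model, scheme, observe = NULL) {
  stopifnot(is(model, "ExchangeModel"), is(scheme, "CpmgScheme"))
  validObject(model); validObject(scheme)
  st <- model@states
  obs <- if (is.null(observe)) st$label[which.max(st$population)] else observe
  oi <- match(obs, st$label)
  if (is.na(oi)) stop("unknown observed state: ", obs)
  necho <- as.integer(round(scheme@nu_cpmg_Hz * scheme@Tcp_s))
  if (any(necho < 1)) stop("nu_cpmg * Tcp rounds to an echo count of 0")
  r2 <- bm_cpmg(st$population, st$R2, st$shift_ppm,
                larmorMHz(scheme@nucleus, scheme@B0_MHz_1H),
                necho, scheme@Tcp_s, buildRateMatrix(model))
  relaxationProfile("cpmg", residue = "sim", nucleus = scheme@nucleus,
                    temperatureK = NA_real_, B0_MHz_1H = scheme@B0_MHz_1H,
                    meta = list(Tcp_s = scheme@Tcp_s, observe = obs),
                    data = data.frame(x = scheme@nu_cpmg_Hz,
                                      y = r2[oi, ], sigma = 1))
}

cpmgRates <- function(populations, R2, shifts_ppm, nucleus, B0_MHz_1H,
                      nu_cpmg_Hz, Tcp_s, K) {
  necho <- as.integer(round(nu_cpmg_Hz * Tcp_s))
  if (any(necho < 1)) stop("nu_cpmg * Tcp rounds to an echo count of 0")
  bm_cpmg(populations, R2, shifts_ppm, larmorMHz(nucleus, B0_MHz_1H),
          necho, Tcp_s, K)
}

#' Trott-Palmer closed-form R1rho
#'
#' Rotating-frame relaxation rate in the asymmetric-population limit
#' (pA >> pB):
#' \deqn{R_{1\rho} = R_1 \cos^2\theta + (R_2 + R_{ex}) \sin^2\theta}
#' \deqn{R_{ex} = \frac{p_B \Delta\omega^2 k_{ex}}
#'                     {(\delta_A + \Delta\omega)^2 + \omega_1^2 + k_{ex}^2}}
#' The tilt angle is \code{theta = atan2(omega1, mean_offset)} where the mean
#' offset is measured from the population-averaged resonance,
#' \code{delta_A + pB * delta_omega}.
#'
#' @param R1,R2 longitudinal/transverse relaxation rates of the dominant
#'   state (s^-1).
#' @param pB minor-state population (fraction).
#' @param delta_omega shift difference between states B and A (rad/s).
#' @param kex exchange rate constant sum (s^-1).
#' @param omega1 spin-lock field strength (rad/s).
#' @param delta_A spin-lock carrier offset from the A-state resonance (rad/s).
#' @return R1rho in s^-1.
#' @examples
#' r1rhoTrottPalmer(1, 10, 0.01, 2*pi*300, 100, 2*pi*1000, 0)  # ~10.083
#' @export
r1rhoTrottPalmer <- function(R1, R2, pB, delta_omega, kex, omega1, delta_A) {
  stopifnot(R1 >= 0, R2 >= 0, kex >= 0, pB >= 0, pB <= 1)
  omega_avg <- delta_A + pB * delta_omega
  if (any(omega1 == 0 & omega_avg == 0))
    stop("tilt angle undefined: omega1 = 0 on resonance")
  theta <- atan2(omega1, omega_avg)
  rex <- pB * delta_omega^2 * kex /
    ((delta_A + delta_omega)^2 + omega1^2 + kex^2)
  R1 * cos(theta)^2 + (R2 + rex) * sin(theta)^2
}

#' Effective transverse relaxation rate from peak intensities
#'
#' \code{R2eff = -(1/Tcp) * log(I/I0)} for a constant-time CPMG element.
#'
#' @param I,I0 peak intensity with and without the relaxation delay; both > 0.
#' @param Tcp constant-time interval (s).
#' @return R2eff in s^-1.
#' @export
r2effFromIntensity <- function(I, I0, Tcp) {
  if (any(I <= 0) || any(I0 <= 0)) stop("intensities must be positive")
  if (Tcp <= 0) stop("Tcp must be positive")
  -log(I / I0) / Tcp
}
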
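#' @include AllClasses.R simulate.R schemes.R
NULL

#' Gaussian noise model for the synthetic generators
#'
#' @slot distribution only "gaussian" is implemented.
#' @slot sigma noise standard deviation (intensity-ratio units for CEST,
#'   s^-1 for CPMG/R1rho).
#' @slot seed RNG seed; identical seeds give byte-identical datasets.
#' @export
setClass("NoiseModel",
  representation(distribution = "character", sigma = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    if (object@sigma < 0) return("sigma must be >= 0")
    if (object@distribution != "gaussian")
      return("only gaussian noise is implemented")
    TRUE
  })

#' @rdname NoiseModel-class
#' @param sigma,seed,distribution see slots.
#' @export
noiseModel <- function(sigma, seed = 1, distribution = "gaussian") {
  new("NoiseModel", distribution = distribution, sigma = sigma, seed = seed)
}

#' Canonical three-state fixture for the lysozyme I59T intermediate
#'
#' Returns the canonical triangular N/I/D exchange fixture for one of the
#' three beta-domain reporter residues at 35 C. Entries tagged
#' \code{"printed"} are the study's published values: the intermediate
#' population of 0.6\%, the pairwise exchange rates kex(N-I) = 27.7 s^-1 and
#' kex(I-D) = 94.3 s^-1, the A42 intermediate 15N shift of 131.4 ppm, the
#' amide 1H shifts (A42 6.90/9.70, I56 9.37/6.61, T59 8.06/6.14 ppm for N/I)
#' and the native-state 15N R2 of 10 s^-1. Entries tagged \code{"fixture"}
#' are frozen arbitrary choices needed to complete the spin system (unprinted
#' shifts, D-state and I-state relaxation rates, kex(N-D) = 5 s^-1 in the
#' slow, HSQC-resolved regime) and are never presented as published values.
#' Native and denatured populations are set equal (0.497 each), consistent
#' with 35 C being the tertiary-structure melting midpoint.
#'
#' @param residue one of "A42", "I56", "T59".
#' @param temperature_C only 35 is supported.
#' @return an [ExchangeFixture-class].
#' @examples
#' fx <- lysozymeFixture("A42")
#' subset(fx@shifts, nucleus == "15N" & state == "I")$ppm  # 131.4
#' @export
lysozymeFixture <- function(residue = c("A42", "I56", "T59"),
                            temperature_C = 35) {
  residue <- match.arg(residue)
  if (!isTRUE(all.equal(temperature_C, 35)))
    stop("fixture only defined at 35 C")

  shifts15N <- switch(residue,
    A42 = data.frame(state = c("N", "I", "D"),
                     ppm = c(123.4, 131.4, 126.8),
                     source = c("fixture", "printed", "fixture")),
    I56 = data.frame(state = c("N", "I", "D"),
                     ppm = c(125.3, 118.0, 122.4),
                     source = "fixture"),
    T59 = data.frame(state = c("N", "I", "D"),
                     ppm = c(112.3, 119.5, 115.8),
                     source = "fixture"))
  shifts1H <- switch(residue,
    A42 = data.frame(state = c("N", "I", "D"), ppm = c(6.90, 9.70, 8.30),
                     source = c("printed", "printed", "fixture")),
    I56 = data.frame(state = c("N", "I", "D"), ppm = c(9.37, 6.61, 8.17),
                     source = c("printed", "printed", "fixture")),
    T59 = data.frame(state = c("N", "I", "D"), ppm = c(8.06, 6.14, 8.21),
                     source = c("printed", "printed", "fixture")))
  shifts <- rbind(cbind(nucleus = "15N", shifts15N),
                  cbind(nucleus = "1H", shifts1H))

  relax <- rbind(
    data.frame(nucleus = "15N", state = c("N", "I", "D"),
               R1 = 1.3, R2 = c(10, 15, 8),
               source = c("printed", "fixture", "fixture")),
    data.frame(nucleus = "1H", state = c("N", "I", "D"),
               R1 = 2.5, R2 = c(15, 20, 12), source = "fixture"))

  new("ExchangeFixture",
      residue = residue, temperatureK = 273.15 + temperature_C,
      populations = c(N = 0.497, I = 0.006, D = 0.497),
      populationSource = c(N = "fixture", I = "printed", D = "fixture"),
      rates = data.frame(from = c("N", "I", "N"), to = c("I", "D", "D"),
                         kex = c(27.7, 94.3, 5),
                         source = c("printed", "printed", "fixture"),
                         stringsAsFactors = FALSE),
      shifts = shifts, relax = relax)
}

#' Three-state exchange fixture with provenance flags
#'
#' @slot residue residue label.
#' @slot temperatureK temperature in Kelvin.
#' @slot populations named state populations.
#' @slot populationSource provenance of each population ("printed" or
#'   "fixture").
#' @slot rates pairwise exchange rates with provenance column.
#' @slot shifts per-nucleus per-state chemical shifts with provenance.
#' @slot relax per-nucleus per-state R1/R2 with provenance.
#' @export
setClass("ExchangeFixture",
  representation(residue = "character", temperatureK = "numeric",
                 populations = "numeric", populationSource = "character",
                 rates = "data.frame", shifts = "data.frame",
                 relax = "data.frame"),
  validity = function(object) {
    if (abs(sum(object@populations) - 1) > 1e-12)
      return("populations must sum to 1")
    TRUE
  })

setMethod("show", "ExchangeFixture", function(object) {
  cat(sprintf("ExchangeFixture %s @ %.2f K: p = (%s)\n", object@residue,
              object@temperatureK,
              paste(sprintf("%s %.3f", names(object@populations),
                            object@populations), collapse = ", ")))
})

#' Build an ExchangeModel from a fixture for one nucleus
#'
#' @param fixture an [ExchangeFixture-class].
#' @param nucleus "15N" or "1H".
#' @return an [ExchangeModel-class] with triangular topology.
#' @export
fixtureModel <- function(fixture, nucleus) {
  sh <- fixture@shifts[fixture@shifts$nucleus == nucleus, ]
  rx <- fixture@relax[fixture@relax$nucleus == nucleus, ]
  if (!nrow(sh)) stop("fixture has no shifts for nucleus ", nucleus)
  labs <- names(fixture@populations)
  exchangeModel(
    states = data.frame(label = labs,
                        population = unname(fixture@populations),
                        shift_ppm = sh$ppm[match(labs, sh$state)],
                        R1 = rx$R1[match(labs, rx$state)],
                        R2 = rx$R2[match(labs, rx$state)]),
    rates = fixture@rates[c("from", "to", "kex")],
    topology = "triangular")
}

.apply_noise <- function(y, noise) {
  if (noise@sigma == 0) y else y + rnorm(length(y), 0, noise@sigma)
}

#' Generate a synthetic CEST dataset from a fixture
#'
#' Simulates CEST profiles with [simulateCest()] for each scheme and observed
#' peak, then adds seeded Gaussian noise to the intensity ratios. The default
#' noise (sigma = 0.005 intensity-ratio units) places a 0.6\% state near the
#' practical detection limit.
#'
#' @param fixture an [ExchangeFixture-class].
#' @param schemes list of [CestScheme-class] objects; default: the 16.4 T
#'   15N grids at B1 = 15 and 60 Hz.
#' @param noise a [NoiseModel-class].
#' @param observe character vector of observed peaks (default both resolved
#'   majority states, N and D).
#' @return a [ProfileDataset-class].
#' @export
generateCestDataset <- function(fixture,
                                schemes = list(defaultCestScheme(16.4, 15),
                                               defaultCestScheme(16.4, 60)),
                                noise = noiseModel(0.005, seed = 1),
                                observe = c("N", "D")) {
  validObject(noise)
  set.seed(noise@seed)
  out <- list()
  for (sc in schemes) {
    model <- fixtureModel(fixture, sc@nucleus)
    for (obs in observe) {
      p <- simulateCest(model, sc, observe = obs)
      p@residue <- fixture@residue
      p@temperatureK <- fixture@temperatureK
      p@data$y <- .apply_noise(p@data$y, noise)
      p@data$sigma <- rep(max(noise@sigma, 1e-6), nrow(p@data))
      out[[length(out) + 1]] <- p
    }
  }
  profileDataset(out)
}

#' Generate a synthetic CPMG dataset from a fixture
#'
#' @inheritParams generateCestDataset
#' @param scheme a [CpmgScheme-class].
#' @param noise noise on R2eff in s^-1 (default sigma = 0.3).
#' @return a [ProfileDataset-class].
#' @export
generateCpmgDataset <- function(fixture, scheme = defaultCpmgScheme(),
                                noise = noiseModel(0.3, seed = 1),
                                observe = c("N", "D")) {
  validObject(noise)
  set.seed(noise@seed)
  model <- fixtureModel(fixture, scheme@nucleus)
  out <- list()
  for (obs in observe) {
    p <- simulateCpmg(model, scheme, observe = obs)
    p@residue <- fixture@residue
    p@temperatureK <- fixture@temperatureK
    p@data$y <- .apply_noise(p@data$y, noise)
    p@data$sigma <- rep(max(noise@sigma, 1e-6), nrow(p@data))
    out[[length(out) + 1]] <- p
  }
  profileDataset(out)
}

#' Generate a multi-temperature two-state CEST series
#'
#' Emulates thermal unfolding monitored by 15N CEST: denatured-state
#' populations follow a van't Hoff curve with midpoint \code{Tm_K} and
#' enthalpy \code{dH_kcal}, per-residue native/denatured 15N shifts are drawn
#' once (seeded) and shared across temperatures, and each temperature yields
#' N- and D-observed profiles for every residue.
#'
#' @param nResidues number of synthetic residues.
#' @param temperaturesK temperature grid (K), non-empty.
#' @param Tm_K van't Hoff midpoint (default 308.15 K, the tertiary-structure
#'   melting temperature).
#' @param dH_kcal van't Hoff enthalpy (kcal/mol).
#' @param kex_ND exchange rate between N and D (s^-1), temperature-constant
#'   in the generator.
#' @param scheme CEST scheme used at every temperature.
#' @param noise a [NoiseModel-class].
#' @return named list of [ProfileDataset-class], keyed by temperature (K),
#'   with attribute \code{"truth"} carrying the generating parameters.
#' @export
generateThermalSeries <- function(nResidues = 10,
                                  temperaturesK = seq(298.15, 318.15, by = 5),
                                  Tm_K = 308.15, dH_kcal = 50, kex_ND = 20,
                                  scheme = defaultCestScheme(16.4, 15),
                                  noise = noiseModel(0.005, seed = 1)) {
  if (!length(temperaturesK)) stop("temperature grid is empty")
  validObject(noise)
  set.seed(noise@seed)
  shiftN <- runif(nResidues, 106, 128)
  shiftD <- shiftN + sample(c(-1, 1), nResidues, TRUE) * runif(nResidues, 2, 4)
  pD <- vantHoffFractionDenatured(temperaturesK, Tm_K, dH_kcal)
  out <- list()
  for (ti in seq_along(temperaturesK)) {
    profs <- list()
    for (r in seq_len(nResidues)) {
      model <- exchangeModel(
        states = data.frame(label = c("N", "D"),
                            population = c(1 - pD[ti], pD[ti]),
                            shift_ppm = c(shiftN[r], shiftD[r]),
                            R1 = 1.3, R2 = c(10, 8)),
        rates = data.frame(from = "N", to = "D", kex = kex_ND),
        topology = "two_state")
      for (obs in c("N", "D")) {
        p <- simulateCest(model, scheme, observe = obs)
        p@residue <- sprintf("R%02d", r)
        p@temperatureK <- temperaturesK[ti]
        p@data$y <- .apply_noise(p@data$y, noise)
        p@data$sigma <- rep(max(noise@sigma, 1e-6), nrow(p@data))
        profs[[length(profs) + 1]] <- p
      }
    }
    out[[sprintf("%.2f", temperaturesK[ti])]] <- profileDataset(profs)
  }
  attr(out, "truth") <- list(Tm_K = Tm_K, dH_kcal = dH_kcal,
                             kex_ND = kex_ND, p_D = pD,
                             shiftN = shiftN, shiftD = shiftD,
                             R2_N = 10, R2_D = 8, R1 = 1.3)
  out
}

#' Van't Hoff denatured fraction
#'
#' \code{f_D(T) = 1 / (1 + exp(dH/R * (1/T - 1/Tm)))} with
#' R = 1.9872e-3 kcal/mol/K; \code{f_D(Tm) = 0.5} by construction.
#'
#' @param T_K temperature(s) in K.
#' @param Tm_K midpoint (K).
#' @param dH_kcal enthalpy (kcal/mol).
#' @export
vantHoffFractionDenatured <- function(T_K, Tm_K, dH_kcal) {
  R <- 1.9872e-3
  1 / (1 + exp(dH_kcal / R * (1 / T_K - 1 / Tm_K)))
}

#' Thermal-denaturation CD curve
#'
#' @slot temperatureK strictly increasing temperatures.
#' @slot ellipticity observed ellipticity (mdeg).
#' @slot wavelength "222" or "270" nm tag.
#' @export
setClass("CdCurve",
  representation(temperatureK = "numeric", ellipticity = "numeric",
                 wavelength = "character"),
  validity = function(object) {
    if (any(diff(object@temperatureK) <= 0))
      return("temperatures must be strictly increasing")
    if (length(object@temperatureK) != length(object@ellipticity))
      return("temperature and ellipticity lengths differ")
    TRUE
  })

#' @rdname CdCurve-class
#' @param temperatureK,ellipticity,wavelength see slots.
#' @export
cdCurve <- function(temperatureK, ellipticity, wavelength = "270") {
  new("CdCurve", temperatureK = temperatureK, ellipticity = ellipticity,
      wavelength = wavelength)
}

#' Generate a synthetic two-state CD melting curve
#'
#' Two-state unfolding with linear native and denatured baselines:
#' \code{theta(T) = (aN + bN T)(1 - fD) + (aD + bD T) fD}, van't Hoff
#' \code{fD}. Noise is Gaussian, scaled to a fraction of the total unfolding
#' amplitude.
#'
#' @param Tm_K,dH_kcal van't Hoff parameters.
#' @param aN,bN,aD,bD baseline intercepts/slopes (mdeg, mdeg/K).
#' @param temperaturesK temperature grid (default 5-95 C in 1 C steps).
#' @param noise_frac Gaussian noise sd as a fraction of the amplitude.
#' @param seed RNG seed.
#' @param wavelength wavelength tag.
#' @return a [CdCurve-class].
#' @export
generateCdCurve <- function(Tm_K = 308.15, dH_kcal = 50,
                            aN = -12, bN = 0.01, aD = -3, bD = 0.005,
                            temperaturesK = seq(278.15, 368.15, by = 1),
                            noise_frac = 0, seed = 1, wavelength = "270") {
  set.seed(seed)
  fD <- vantHoffFractionDenatured(temperaturesK, Tm_K, dH_kcal)
  theta <- (aN + bN * temperaturesK) * (1 - fD) +
           (aD + bD * temperaturesK) * fD
  amp <- abs((aN + bN * Tm_K) - (aD + bD * Tm_K))
  if (noise_frac > 0) theta <- theta + rnorm(length(theta), 0, noise_frac * amp)
  cdCurve(temperaturesK, theta, wavelength)
}
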
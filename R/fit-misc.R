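#' @include fit-global.R fixtures.R
NULL

#' Two-state thermal-unfolding fit across temperatures
#'
#' Globally fits multi-temperature CEST datasets to a two-state N/D model:
#' populations and kex are free per temperature, chemical shifts (and
#' relaxation rates) are local per residue and, by default, shared across
#' temperatures. No van't Hoff constraint links the temperatures.
#'
#' @param datasets named list of [ProfileDataset-class] objects keyed by
#'   temperature; at least two temperatures.
#' @param shareShifts share per-residue shifts across temperatures.
#' @param ... passed to [globalFit()].
#' @return list with \code{fit} (the [FitResult-class]), \code{populations}
#'   (data.frame: temperature_K, p_N, p_D, kex_ND) and \code{R2} (per
#'   residue/state transverse rates).
#' @export
fitTwoStateThermal <- function(datasets, shareShifts = TRUE, ...) {
  if (length(datasets) < 2) stop("need datasets at >= 2 temperatures")
  single <- vapply(datasets, function(d) length(d@profiles) == 1, logical(1))
  if (any(single))
    warning("temperature(s) with a single profile: expect wide uncertainty")
  all_prof <- unlist(lapply(datasets, function(d) d@profiles),
                     recursive = FALSE)
  # staged initialization: each temperature is first fitted on its own
  # (a well-conditioned single-temperature problem), and the per-T
  # populations/rates plus averaged shifts seed the combined fit
  init <- tryCatch({
    acc <- c()
    for (d in datasets) {
      pre <- globalFit(d, "two_state", nstarts = 1, computeSd = FALSE,
                       maxit = 100)
      vals <- setNames(pre@parameters$value, pre@parameters$name)
      tl <- sprintf("%.2fK", d@profiles[[1]]@temperatureK)
      glob <- grepl("^(p_|kex_)", names(vals))
      names(vals)[glob] <- paste0(names(vals)[glob], "_", tl)
      acc <- c(acc, vals)
    }
    loc <- acc[!grepl("_\\d+\\.\\d+K$", names(acc))]
    c(acc[grepl("_\\d+\\.\\d+K$", names(acc))],
      tapply(loc, names(loc), mean))
  }, error = function(e) NULL)
  fit <- globalFit(profileDataset(all_prof), topology = "two_state",
                   shareShifts = shareShifts, init = init, ...)
  pt <- fit@parameters
  temps <- sort(unique(vapply(all_prof, function(p) p@temperatureK,
                              numeric(1))))
  tl <- sprintf("%.2fK", temps)
  pop <- data.frame(
    temperature_K = temps,
    p_N = vapply(tl, function(t) pt$value[pt$name == paste0("p_N_", t)],
                 numeric(1)),
    p_D = vapply(tl, function(t) pt$value[pt$name == paste0("p_D_", t)],
                 numeric(1)),
    kex_ND = vapply(tl, function(t)
      pt$value[pt$name == paste0("kex_ND_", t)], numeric(1)))
  r2 <- pt[grepl("^R2_", pt$name), c("name", "value", "sd")]
  list(fit = fit, populations = pop, R2 = r2)
}

#' Two-state CD melting-curve fit with linear baselines
#'
#' Fits \code{theta(T) = (aN + bN T)(1 - fD) + (aD + bD T) fD} with the
#' van't Hoff denatured fraction
#' \code{fD = 1 / (1 + exp(dH/R (1/T - 1/Tm)))}. \code{fD(Tm) = 0.5} by
#' construction.
#'
#' @param curve a [CdCurve-class] with at least 8 points spanning the
#'   transition.
#' @return list with \code{Tm_K}, \code{dH_kcal}, baseline coefficients
#'   (\code{aN}, \code{bN}, \code{aD}, \code{bD}), \code{fD} evaluated on the
#'   input grid, \code{identifiable} flag and the chi-square.
#' @export
fitCdTwoState <- function(curve) {
  stopifnot(is(curve, "CdCurve"))
  Tk <- curve@temperatureK
  y <- curve@ellipticity
  if (length(Tk) < 8) stop("need >= 8 points spanning the transition")

  model <- function(p) {
    fD <- vantHoffFractionDenatured(Tk, p[1], p[2])
    (p[3] + p[4] * Tk) * (1 - fD) + (p[5] + p[6] * Tk) * fD
  }
  # crude inits: midpoint near the steepest change, baselines from the ends
  i <- which.max(abs(diff(.running_mean(y, 5))))
  ne <- max(3, length(Tk) %/% 5)
  cN <- stats::coef(stats::lm(y[1:ne] ~ Tk[1:ne]))
  cD <- stats::coef(stats::lm(y[(length(y) - ne + 1):length(y)] ~
                              Tk[(length(y) - ne + 1):length(y)]))
  p0 <- c(Tm = Tk[i], dH = 40, aN = unname(cN[1]), bN = unname(cN[2]),
          aD = unname(cD[1]), bD = unname(cD[2]))
  fit <- minpack.lm::nls.lm(
    par = p0, fn = function(p) y - model(p),
    lower = c(min(Tk), 1, -Inf, -Inf, -Inf, -Inf),
    upper = c(max(Tk), 500, Inf, Inf, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  fD <- vantHoffFractionDenatured(Tk, p[1], p[2])
  # non-identifiable when the transition midpoint sits at the grid edge or
  # the baselines never separate
  identifiable <- p[1] > min(Tk) + 2 && p[1] < max(Tk) - 2 &&
    max(fD) > 0.75 && min(fD) < 0.25
  if (!identifiable)
    warning("no clear transition in the fitted range; parameters are not identifiable")
  list(Tm_K = unname(p[1]), dH_kcal = unname(p[2]), aN = unname(p[3]),
       bN = unname(p[4]), aD = unname(p[5]), bD = unname(p[6]), fD = fD,
       identifiable = identifiable, chi2 = fit$deviance)
}

#' Global fit of on-/off-resonance R1rho dispersion
#'
#' Least-squares fit of the rotating-frame relaxation closed form (see
#' [r1rhoTrottPalmer()]). The amplitude of the exchange contribution is only
#' identifiable as the composite \code{phi = pB * delta_omega^2}, which is
#' what is reported, together with kex and R2. The shift difference entering
#' the off-resonance denominator is fitted as a weakly determined nuisance
#' parameter.
#'
#' @param points data.frame with columns \code{R1rho} (s^-1),
#'   \code{omega1} (rad/s), \code{deltaA} (rad/s), optionally \code{sigma}.
#' @param R1 longitudinal rate, held fixed (s^-1).
#' @return list with \code{phi} (rad^2/s^2), \code{kex}, \code{R2},
#'   \code{delta_omega}, fitted values and residuals.
#' @export
fitR1rho <- function(points, R1) {
  stopifnot(all(c("R1rho", "omega1", "deltaA") %in% names(points)))
  if (nrow(points) < 6) stop("need >= 6 points")
  if (all(points$deltaA == 0))
    warning("only on-resonance points: pB/delta_omega strongly degenerate")
  sig <- if ("sigma" %in% names(points)) points$sigma else rep(1, nrow(points))

  model <- function(p) {
    phi <- 10^p[1]; kex <- 10^p[2]; r2 <- 10^p[3]; dw <- p[4]
    pB_eff <- phi / dw^2
    r1rhoTrottPalmer(R1, r2, pmin(pB_eff, 0.5), dw, kex, points$omega1,
                     points$deltaA)
  }
  p0 <- c(log10(0.01 * (2 * pi * 200)^2), log10(500),
          log10(max(min(points$R1rho), 1)), 2 * pi * 200)
  fit <- minpack.lm::nls.lm(
    par = p0, fn = function(p) (points$R1rho - model(p)) / sig,
    lower = c(-2, 0, -1, 2 * pi * 1), upper = c(10, 4.5, 2.7, 2 * pi * 5000),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- fit$par
  list(phi = 10^p[1], kex = 10^p[2], R2 = 10^p[3], delta_omega = p[4],
       fitted = model(p), residuals = points$R1rho - model(p),
       chi2 = fit$deviance, converged = fit$info %in% 1:4)
}
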
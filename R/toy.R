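#' @include geometry.R
NULL

#' Build the native helix-hairpin toy model
#'
#' Deterministic ~30-bead coarse-grained fold: an ideal 14-bead alpha-helix
#' (2.3 Angstrom radius, 1.5 Angstrom rise, 100 degrees per bead), a 2-bead
#' loop, and a 14-bead antiparallel hairpin packed against the helix face.
#' The potential is Go-like: stiff harmonic bonds on 1-2 distances, softer
#' harmonics on 1-3 distances (angle surrogates), 12-10 attractive wells at
#' every native contact (|i-j| >= 4, native distance < 8 Angstrom), and a
#' generic r^-12 repulsion between all remaining non-local pairs, so the
#' native structure is the potential's global minimum by construction.
#' The ratchet collective-variable pairs reuse [rmdPairs()] with the
#' index-separation threshold rescaled to the bead chain (> 5), and Q uses
#' the native-contact pairs.
#'
#' @param seed unused placeholder for interface symmetry; the fixture is
#'   fully deterministic.
#' @return a [ToyModel-class].
#' @export
buildToyNative <- function(seed = 1) {
  # helix
  k <- 0:13
  th <- k * 100 * pi / 180
  helix <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * k)
  # loop: interpolate from helix end toward the first strand bead
  a_top <- c(6.3, 0, 16)
  loop <- rbind(helix[14, ] + (a_top - helix[14, ]) / 3,
                helix[14, ] + 2 * (a_top - helix[14, ]) / 3)
  strandA <- cbind(6.3, 0, 16 - 3.8 * (0:6))
  strandB <- cbind(6.3, 3.6, -6.8 + 1.2 + 3.8 * (0:6))
  native <- rbind(helix, loop, strandA, strandB)
  n <- nrow(native)
  atoms <- data.frame(name = "CA", element = "C", resid = seq_len(n),
                      resname = "GLY", chain = "A")

  dist_ij <- function(i, j) sqrt(sum((native[i, ] - native[j, ])^2))
  bonds <- data.frame(i = 1:(n - 1), j = 2:n)
  bonds$r0 <- vapply(seq_len(nrow(bonds)), function(b)
    dist_ij(bonds$i[b], bonds$j[b]), numeric(1))
  bonds$k <- 200
  ang <- data.frame(i = 1:(n - 2), j = 3:n)
  ang$r0 <- vapply(seq_len(nrow(ang)), function(b)
    dist_ij(ang$i[b], ang$j[b]), numeric(1))
  ang$k <- 20
  bonds <- rbind(bonds, ang)

  dm <- as.matrix(stats::dist(native))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  sep <- idx[, 2] - idx[, 1]
  nat <- idx[sep >= 4 & dm[idx] < 8, , drop = FALSE]
  natpairs <- data.frame(i = nat[, 1], j = nat[, 2], sigma = dm[nat])
  repp <- idx[sep >= 4 & dm[idx] >= 8, , drop = FALSE]
  reppairs <- data.frame(i = repp[, 1], j = repp[, 2])

  cvpairs <- rmdPairs(native, atoms, cutoff = 12.0, minIndexSep = 5)
  qpairs <- natpairs[, c("i", "j")]
  qpairs$r0 <- natpairs$sigma

  new("ToyModel", native = native, bonds = bonds, natpairs = natpairs,
      reppairs = reppairs, cvpairs = cvpairs, qpairs = qpairs,
      params = list(kbond = 200, eps_nat = 1, eps_rep = 1, rep_sigma = 4.0,
                    cv_r0 = 7.5, q_beta = 5, q_lambda = 1.5))
}

#' Potential energy of a toy-model conformation
#'
#' @param model a [ToyModel-class].
#' @param frame bead coordinates (defaults to the native frame).
#' @return potential energy (model units).
#' @export
toyEnergy <- function(model, frame = model@native) {
  toy_energy_cpp(frame,
                 as.matrix(model@bonds[, c("i", "j")]) - 1L, model@bonds$r0,
                 model@params$kbond,
                 as.matrix(model@natpairs[, c("i", "j")]) - 1L,
                 model@natpairs$sigma, model@params$eps_nat,
                 as.matrix(model@reppairs[, c("i", "j")]) - 1L,
                 model@params$rep_sigma, model@params$eps_rep)
}

#' Overdamped Langevin configuration
#'
#' @param dt timestep; \code{dt * kbond / gamma} must stay below 0.25 for
#'   the stiffest bond (checked at run time).
#' @param gamma friction coefficient.
#' @param kT thermal energy (model units).
#' @param nsteps step budget.
#' @param save_every frame/series saving stride.
#' @param seed RNG seed (R's RNG; identical seeds give identical
#'   trajectories).
#' @return list of class "langevinConfig".
#' @export
langevinConfig <- function(dt = 0.005, gamma = 10, kT = 1.0, nsteps = 20000,
                           save_every = 100, seed = 1) {
  structure(list(dt = dt, gamma = gamma, kT = kT, nsteps = nsteps,
                 save_every = save_every, seed = seed),
            class = "langevinConfig")
}

#' Run (optionally ratchet-biased) overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of the toy model under its Go-like potential,
#' with the ratchet-and-pawl bias along the contact-map collective variable
#' when \code{bias = TRUE}: the bias potential \code{kappa/2 (rho - rho_m)^2}
#' is active only while \code{rho} exceeds its running minimum, so the
#' biased energy is identically zero whenever the system progresses toward
#' the CV target. With \code{kappa = 0} the biased integrator is bit-
#' identical to the unbiased one under equal seeds.
#'
#' @param model a [ToyModel-class].
#' @param start starting coordinates (default native).
#' @param config a [langevinConfig()].
#' @param bias enable the ratchet bias.
#' @param kappa bias force constant (toy CV units; not transferable to
#'   all-atom values).
#' @param cv_target CV target value (0 = native contact map).
#' @param blow_threshold abort when any coordinate exceeds this magnitude.
#' @return list with \code{frames} (nbeads x 3 x nsaved array),
#'   \code{series} (data.frame: step, Q, CV, rho, rho_min, bias_energy),
#'   \code{ok} (FALSE when the integration blew up) and \code{rho_min}.
#' @export
runLangevin <- function(model, start = model@native, config = langevinConfig(),
                        bias = FALSE, kappa = 0.2, cv_target = 0,
                        blow_threshold = 1e4) {
  stopifnot(is(model, "ToyModel"))
  if (config$dt * model@params$kbond / config$gamma >= 0.25)
    stop("timestep unstable for the stiffest bond: reduce dt or raise gamma")
  set.seed(config$seed)
  res <- langevin_rmd_cpp(
    start,
    as.matrix(model@bonds[, c("i", "j")]) - 1L, model@bonds$r0,
    model@params$kbond,
    as.matrix(model@natpairs[, c("i", "j")]) - 1L, model@natpairs$sigma,
    model@params$eps_nat,
    as.matrix(model@reppairs[, c("i", "j")]) - 1L, model@params$rep_sigma,
    model@params$eps_rep,
    as.matrix(model@cvpairs[, c("i", "j")]) - 1L, model@cvpairs$cnat,
    model@params$cv_r0,
    as.matrix(model@qpairs[, c("i", "j")]) - 1L, model@qpairs$r0,
    model@params$q_beta, model@params$q_lambda,
    config$dt, config$gamma, config$kT, as.integer(config$nsteps),
    as.integer(config$save_every),
    isTRUE(bias), kappa, cv_target, blow_threshold)
  if (!res$ok)
    warning("integration aborted: coordinates exceeded the blow-up threshold")
  series <- as.data.frame(res$series)
  names(series) <- c("step", "Q", "CV", "rho", "rho_min", "bias_energy")
  list(frames = res$frames, series = series, ok = res$ok,
       rho_min = res$rho_min)
}

#' High-temperature unfolding of the toy model
#'
#' Runs unbiased dynamics at elevated temperature from the native state until
#' the fraction of native contacts drops below \code{qTarget} (default 0.1),
#' emulating the deletion of native stabilisation, and returns the last
#' frame. Chain connectivity is preserved by the bonded terms.
#'
#' @param model a [ToyModel-class].
#' @param kT_high unfolding temperature.
#' @param steps_per_chunk,max_chunks unfolding budget.
#' @param qTarget target fraction of native contacts.
#' @param seed RNG seed.
#' @return bead coordinate matrix with Q < qTarget.
#' @export
unfoldToy <- function(model, kT_high = 15, steps_per_chunk = 4000,
                      max_chunks = 40, qTarget = 0.1, seed = 1) {
  x <- model@native
  for (ch in seq_len(max_chunks)) {
    cfg <- langevinConfig(kT = kT_high, nsteps = steps_per_chunk,
                          save_every = steps_per_chunk, seed = seed + ch)
    run <- runLangevin(model, start = x, config = cfg)
    ns <- dim(run$frames)[3]
    x <- run$frames[, , ns]
    if (qFraction(x, model@qpairs, model@params$q_beta,
                  model@params$q_lambda) < qTarget)
      return(x)
  }
  stop("failed to unfold below Q = ", qTarget, " within the budget")
}

#' Fraction of trajectories that reach the native state
#'
#' A trajectory succeeds when any saved frame passes [nativeStateTest()]
#' against the native reference.
#'
#' @param runs list of [runLangevin()] results.
#' @param native native coordinates.
#' @param cutoff RMSD cutoff in Angstrom (toy default 2.0; configurable).
#' @return success fraction in [0, 1].
#' @export
foldingSuccessRate <- function(runs, native, cutoff = 2.0) {
  stopifnot(length(runs) >= 1)
  hit <- vapply(runs, function(run) {
    nf <- dim(run$frames)[3]
    for (f in seq_len(nf)) {
      if (superposedRmsd(run$frames[, , f], native) <= cutoff) return(TRUE)
    }
    FALSE
  }, logical(1))
  mean(hit)
}

#' Convert a toy trajectory to a StructureEnsemble
#'
#' @param model a [ToyModel-class].
#' @param frames nbeads x 3 x nframes array (e.g. from [runLangevin()]).
#' @return a [StructureEnsemble-class] (one CA bead per residue), writable
#'   with [writePdbEnsemble()].
#' @export
toyEnsemble <- function(model, frames) {
  n <- nrow(model@native)
  atoms <- data.frame(name = "CA", element = "C", resid = seq_len(n),
                      resname = "GLY", chain = "A")
  structureEnsemble(atoms, frames)
}
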
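#' @include foldex-package.R
NULL

# ---- chemical exchange ------------------------------------------------------

#' Multi-state chemical exchange model
#'
#' An \code{ExchangeModel} holds the thermodynamic and spectroscopic state of
#' an exchanging spin system for one probed nucleus: per-state populations,
#' chemical shifts (ppm), longitudinal and transverse relaxation rates, and a
#' pairwise exchange-rate topology. Pairwise rates are stored as \code{kex}
#' (the sum of forward and reverse rate constants for that edge); directional
#' rates follow from detailed balance, so the stationarity and
#' detailed-balance invariants hold by construction.
#'
#' @slot states data.frame with columns \code{label}, \code{population},
#'   \code{shift_ppm}, \code{R1}, \code{R2}.
#' @slot rates data.frame with columns \code{from}, \code{to}, \code{kex}
#'   (s^-1), one row per topology edge.
#' @slot topology character tag, e.g. \code{"two_state"}, \code{"N-I-D"},
#'   \code{"triangular"}.
#'
#' @seealso [exchangeModel()], [buildRateMatrix()]
#' @export
setClass("ExchangeModel",
  representation(states = "data.frame", rates = "data.frame",
                 topology = "character"),
  validity = function(object) {
    st <- object@states
    msg <- character()
    need <- c("label", "population", "shift_ppm", "R1", "R2")
    if (!all(need %in% names(st)))
      return(paste("states must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(st$label)) msg <- c(msg, "state labels must be unique")
    if (any(st$population < 0 | st$population > 1))
      msg <- c(msg, "populations must lie in [0, 1]")
    if (abs(sum(st$population) - 1) > 1e-12)
      msg <- c(msg, "populations must sum to 1 (tolerance 1e-12)")
    if (any(st$R1 < 0) || any(st$R2 < 0))
      msg <- c(msg, "relaxation rates must be non-negative")
    rt <- object@rates
    if (nrow(rt)) {
      if (!all(c("from", "to", "kex") %in% names(rt)))
        return("rates must have columns from, to, kex")
      if (any(rt$kex < 0)) msg <- c(msg, "kex must be non-negative")
      if (!all(c(rt$from, rt$to) %in% st$label))
        msg <- c(msg, "rate edges must reference state labels")
      if (any(rt$from == rt$to)) msg <- c(msg, "self-edges are not allowed")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

#' Construct an ExchangeModel
#'
#' @param states data.frame with columns \code{label}, \code{population},
#'   \code{shift_ppm}, \code{R1}, \code{R2}.
#' @param rates data.frame with columns \code{from}, \code{to}, \code{kex};
#'   may be empty for a non-exchanging system.
#' @param topology character tag describing the exchange topology.
#' @return An [ExchangeModel-class] object.
#' @examples
#' m <- exchangeModel(
#'   states = data.frame(label = c("N", "D"), population = c(0.5, 0.5),
#'                       shift_ppm = c(120, 123), R1 = 1.5, R2 = c(10, 8)),
#'   rates = data.frame(from = "N", to = "D", kex = 100),
#'   topology = "two_state")
#' buildRateMatrix(m)
#' @export
exchangeModel <- function(states, rates = data.frame(from = character(),
                                                     to = character(),
                                                     kex = numeric()),
                          topology = "custom") {
  states$label <- as.character(states$label)
  if (nrow(rates)) {
    rates$from <- as.character(rates$from)
    rates$to <- as.character(rates$to)
  }
  new("ExchangeModel", states = states, rates = rates, topology = topology)
}

#' CEST acquisition scheme
#'
#' @slot B0_MHz_1H spectrometer field expressed as the 1H Larmor frequency.
#' @slot nucleus probed nucleus label ("15N", "1H", "13C").
#' @slot B1_Hz saturation field strength.
#' @slot Tex_s saturation time.
#' @slot offsets_ppm strictly monotone grid of saturation offsets.
#' @export
setClass("CestScheme",
  representation(B0_MHz_1H = "numeric", nucleus = "character",
                 B1_Hz = "numeric", Tex_s = "numeric",
                 offsets_ppm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@B1_Hz <= 0) msg <- c(msg, "B1_Hz must be > 0")
    if (object@Tex_s < 0) msg <- c(msg, "Tex_s must be >= 0")
    d <- diff(object@offsets_ppm)
    if (length(d) && !(all(d > 0) || all(d < 0)))
      msg <- c(msg, "offsets_ppm must be strictly monotone")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

#' @rdname CestScheme-class
#' @param B0_MHz_1H,nucleus,B1_Hz,Tex_s,offsets_ppm see slots.
#' @export
cestScheme <- function(B0_MHz_1H, nucleus, B1_Hz, Tex_s, offsets_ppm) {
  new("CestScheme", B0_MHz_1H = B0_MHz_1H, nucleus = nucleus, B1_Hz = B1_Hz,
      Tex_s = Tex_s, offsets_ppm = offsets_ppm)
}

#' CPMG acquisition scheme
#'
#' Constant-time CPMG: the echo count for each pulsing frequency is
#' \code{n = round(nu * Tcp)} and the grid must give \code{n >= 1}.
#'
#' @slot B0_MHz_1H field as 1H MHz.
#' @slot nucleus probed nucleus label.
#' @slot Tcp_s constant-time relaxation interval (s).
#' @slot nu_cpmg_Hz refocusing frequencies (Hz).
#' @export
setClass("CpmgScheme",
  representation(B0_MHz_1H = "numeric", nucleus = "character",
                 Tcp_s = "numeric", nu_cpmg_Hz = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@Tcp_s <= 0) msg <- c(msg, "Tcp_s must be > 0")
    n <- round(object@nu_cpmg_Hz * object@Tcp_s)
    if (any(n < 1))
      msg <- c(msg, "every nu_cpmg * Tcp must round to an echo count >= 1")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

#' @rdname CpmgScheme-class
#' @param B0_MHz_1H,nucleus,Tcp_s,nu_cpmg_Hz see slots.
#' @export
cpmgScheme <- function(B0_MHz_1H, nucleus, Tcp_s, nu_cpmg_Hz) {
  new("CpmgScheme", B0_MHz_1H = B0_MHz_1H, nucleus = nucleus, Tcp_s = Tcp_s,
      nu_cpmg_Hz = nu_cpmg_Hz)
}

#' One measured or simulated relaxation profile
#'
#' @slot experiment one of "cest", "cpmg", "r1rho".
#' @slot residue residue label, e.g. "A42".
#' @slot nucleus probed nucleus, e.g. "15N".
#' @slot temperatureK sample temperature (K).
#' @slot B0_MHz_1H field as 1H MHz.
#' @slot meta list of acquisition metadata (B1_Hz, Tex_s, Tcp_s, observe, ...).
#' @slot data data.frame with columns \code{x}, \code{y}, \code{sigma}.
#' @export
setClass("RelaxationProfile",
  representation(experiment = "character", residue = "character",
                 nucleus = "character", temperatureK = "numeric",
                 B0_MHz_1H = "numeric", meta = "list", data = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!object@experiment %in% c("cest", "cpmg", "r1rho"))
      msg <- c(msg, "experiment must be cest, cpmg or r1rho")
    if (!all(c("x", "y", "sigma") %in% names(object@data)))
      msg <- c(msg, "data must have columns x, y, sigma")
    else if (any(object@data$sigma <= 0))
      msg <- c(msg, "sigma must be > 0")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

relaxationProfile <- function(experiment, residue, nucleus, temperatureK,
                              B0_MHz_1H, meta, data) {
  new("RelaxationProfile", experiment = experiment, residue = residue,
      nucleus = nucleus, temperatureK = temperatureK, B0_MHz_1H = B0_MHz_1H,
      meta = meta, data = data)
}

#' A collection of relaxation profiles entering one global fit
#'
#' @slot profiles list of [RelaxationProfile-class] objects.
#' @export
setClass("ProfileDataset",
  representation(profiles = "list"),
  validity = function(object) {
    ok <- vapply(object@profiles, function(p) is(p, "RelaxationProfile"),
                 logical(1))
    if (!all(ok)) "all elements must be RelaxationProfile objects" else TRUE
  })

#' @rdname ProfileDataset-class
#' @param profiles list of RelaxationProfile objects.
#' @export
profileDataset <- function(profiles = list()) {
  new("ProfileDataset", profiles = profiles)
}

#' Result of a nonlinear exchange-model fit
#'
#' @slot topology topology tag the data were fitted to.
#' @slot parameters data.frame with columns \code{name}, \code{value},
#'   \code{sd}.
#' @slot stats list with \code{chi2}, \code{reduced_chi2}, \code{bic},
#'   \code{aic}, \code{n_points}, \code{n_params}.
#' @slot convergence list of optimizer diagnostics (converged flag, message,
#'   iterations, start index of the winning multistart).
#' @export
setClass("FitResult",
  representation(topology = "character", parameters = "data.frame",
                 stats = "list", convergence = "list"))

# ---- structures -------------------------------------------------------------

#' Structure ensemble: topology plus coordinate frames
#'
#' Coordinates are in Angstrom throughout. \code{atoms} carries one row per
#' atom (name, element, resid, resname, chain); \code{coords} is an
#' \code{natoms x 3 x nframes} array.
#'
#' @slot atoms data.frame describing the topology.
#' @slot coords numeric array, dim \code{c(natoms, 3, nframes)}.
#' @export
setClass("StructureEnsemble",
  representation(atoms = "data.frame", coords = "array"),
  validity = function(object) {
    need <- c("name", "element", "resid", "resname", "chain")
    if (!all(need %in% names(object@atoms)))
      return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    d <- dim(object@coords)
    if (length(d) != 3 || d[2] != 3)
      return("coords must be an natoms x 3 x nframes array")
    if (d[1] != nrow(object@atoms))
      return("coordinate count must match the topology in every frame")
    if (is.unsorted(object@atoms$resid))
      return("residue indices must be non-decreasing")
    TRUE
  })

#' @rdname StructureEnsemble-class
#' @param atoms topology data.frame.
#' @param coords natoms x 3 matrix (single frame) or natoms x 3 x nframes
#'   array.
#' @export
structureEnsemble <- function(atoms, coords) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  new("StructureEnsemble", atoms = atoms, coords = coords)
}

#' Binned 2-D free-energy surface over two collective variables
#'
#' @slot xmids,ymids bin midpoints of the two collective variables.
#' @slot free free-energy grid in kJ/mol, min-shifted to zero; empty bins are
#'   \code{Inf}.
#' @slot temperatureK temperature used in -RT log(density).
#' @slot sigma Gaussian smoothing width in bins.
#' @slot cvNames names of the two collective variables.
#' @export
setClass("Landscape",
  representation(xmids = "numeric", ymids = "numeric", free = "matrix",
                 temperatureK = "numeric", sigma = "numeric",
                 cvNames = "character"),
  validity = function(object) {
    f <- object@free
    if (nrow(f) != length(object@xmids) || ncol(f) != length(object@ymids))
      return("free-energy grid dimensions must match bin midpoints")
    if (any(is.finite(f) & f < 0)) return("finite bins must be >= 0 after shift")
    TRUE
  })

# ---- toy model --------------------------------------------------------------

#' Coarse-grained Go-like bead model for the ratchet-and-pawl demonstration
#'
#' @slot native natoms x 3 matrix of native bead coordinates (Angstrom).
#' @slot bonds data.frame (i, j, r0) of harmonic bonded terms (1-2 bonds and
#'   1-3 angle surrogates).
#' @slot natpairs data.frame (i, j, sigma) of native-contact 12-10 wells.
#' @slot reppairs data.frame (i, j) of generic repulsive pairs.
#' @slot cvpairs data.frame (i, j, r0, cnat) defining the ratchet collective
#'   variable.
#' @slot qpairs data.frame (i, j, r0) defining the native-contact fraction Q.
#' @slot params list of force-field constants (kbond, eps_nat, eps_rep,
#'   rep_sigma, cv_r0, q_beta, q_lambda).
#' @export
setClass("ToyModel",
  representation(native = "matrix", bonds = "data.frame",
                 natpairs = "data.frame", reppairs = "data.frame",
                 cvpairs = "data.frame", qpairs = "data.frame",
                 params = "list"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "ExchangeModel", function(object) {
  cat(sprintf("ExchangeModel (%s): %d states, %d exchange edges\n",
              object@topology, nrow(object@states), nrow(object@rates)))
  print(object@states, row.names = FALSE)
  if (nrow(object@rates)) print(object@rates, row.names = FALSE)
})

setMethod("show", "RelaxationProfile", function(object) {
  cat(sprintf("RelaxationProfile: %s %s %s, %.1f K, %.0f MHz, %d points\n",
              object@experiment, object@residue, object@nucleus,
              object@temperatureK, object@B0_MHz_1H, nrow(object@data)))
})

setMethod("show", "ProfileDataset", function(object) {
  exps <- vapply(object@profiles, function(p) p@experiment, character(1))
  cat(sprintf("ProfileDataset: %d profiles (%s), %d points total\n",
              length(object@profiles),
              paste(sprintf("%s: %d", names(table(exps)), table(exps)),
                    collapse = ", "),
              sum(vapply(object@profiles, function(p) nrow(p@data),
                         integer(1)))))
})

setMethod("show", "FitResult", function(object) {
  s <- object@stats
  cat(sprintf(
    "FitResult [%s]: chi2 = %.2f, red. chi2 = %.3f, BIC = %.1f, AIC = %.1f (n = %d, k = %d)\n",
    object@topology, s$chi2, s$reduced_chi2, s$bic, s$aic, s$n_points,
    s$n_params))
  if (!isTRUE(object@convergence$converged))
    cat("  warning: optimizer did not report convergence\n")
})

setMethod("show", "StructureEnsemble", function(object) {
  cat(sprintf("StructureEnsemble: %d atoms, %d residues, %d frame(s)\n",
              nrow(object@atoms), length(unique(object@atoms$resid)),
              dim(object@coords)[3]))
})

setMethod("show", "Landscape", function(object) {
  cat(sprintf(
    "Landscape over (%s, %s): %d x %d bins, sigma = %g, T = %.0f K\n",
    object@cvNames[1], object@cvNames[2], length(object@xmids),
    length(object@ymids), object@sigma, object@temperatureK))
})

setMethod("show", "ToyModel", function(object) {
  cat(sprintf(
    "ToyModel: %d beads, %d bonded terms, %d native contacts, %d CV pairs\n",
    nrow(object@native), nrow(object@bonds), nrow(object@natpairs),
    nrow(object@cvpairs)))
})
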
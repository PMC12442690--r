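#' @include structure.R
NULL

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body superposition of \code{mobile} onto \code{ref} by SVD
#' of the cross-covariance matrix, with the reflection corrected so the
#' rotation is proper (det = +1). When \code{selection} is given, the
#' transform is determined on (and the RMSD reported over) the selected
#' atoms, but the full coordinate set is transformed.
#'
#' @param mobile,ref n x 3 coordinate matrices (Angstrom).
#' @param selection optional integer vector of atom indices.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3),
#'   \code{rmsd} (Angstrom) and \code{coords} (transformed mobile).
#' @export
kabschSuperpose <- function(mobile, ref, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  m <- mobile[selection, , drop = FALSE]
  r <- ref[selection, , drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 selected atoms")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  sv <- tryCatch(svd(crossprod(mc, rc)), error = function(e)
    stop("degenerate selection: ", conditionMessage(e)))
  if (sv$d[2] < 1e-10) stop("degenerate (collinear) selection")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- mc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  coords <- sweep(sweep(mobile, 2, cm) %*% t(R), 2, cr, "+")
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)),
       rmsd = rmsd, coords = coords)
}

#' Alpha-carbon RMSD after superposition
#'
#' @param mobile,ref coordinate matrices.
#' @param selection atom indices used for fitting and RMSD (e.g. CA atoms);
#'   default all.
#' @return RMSD in Angstrom.
#' @export
superposedRmsd <- function(mobile, ref, selection = NULL) {
  kabschSuperpose(mobile, ref, selection)$rmsd
}

#' Native-state membership test
#'
#' A frame counts as native when its superposed alpha-carbon RMSD to the
#' reference is at most \code{cutoff} (boundary inclusive).
#'
#' @param frame,ref coordinate matrices.
#' @param selection CA indices (default: all atoms, for CA-only models).
#' @param cutoff RMSD threshold in Angstrom (default 3.0).
#' @return logical.
#' @export
nativeStateTest <- function(frame, ref, selection = NULL, cutoff = 3.0) {
  superposedRmsd(frame, ref, selection) <= cutoff
}

.pair_dist <- function(coords, i, j) {
  sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
}

#' Native contact pairs for the fraction of native contacts Q
#'
#' Heavy-atom pairs within \code{cutoff} (4.5 Angstrom) in the native frame
#' between residues separated by more than 3 in sequence.
#'
#' @param native n x 3 native coordinates.
#' @param atoms topology data.frame (columns \code{element}, \code{resid}).
#' @param cutoff native-distance cutoff in Angstrom.
#' @param minResSep minimum residue separation (pairs with
#'   \code{|resid_i - resid_j| > minResSep} are kept).
#' @return data.frame with columns \code{i}, \code{j} (atom indices,
#'   \code{i < j}) and \code{r0} (native distance).
#' @export
nativePairsQ <- function(native, atoms, cutoff = 4.5, minResSep = 3) {
  heavy <- which(!(atoms$element %in% c("H", "D")))
  cp <- .candidate_pairs(native, heavy, cutoff)
  keep <- abs(atoms$resid[cp$i] - atoms$resid[cp$j]) > minResSep
  out <- cp[keep, , drop = FALSE]
  if (!nrow(out)) stop("no native contact pairs found")
  rownames(out) <- NULL
  out
}

# all pairs among `sel` with distance <= cutoff, as data.frame(i, j, r0)
.candidate_pairs <- function(coords, sel, cutoff) {
  x <- coords[sel, , drop = FALSE]
  dm <- as.matrix(stats::dist(x))
  idx <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
  data.frame(i = sel[idx[, 1]], j = sel[idx[, 2]],
             r0 = dm[idx])
}

#' Fraction of native contacts Q
#'
#' \deqn{Q(X) = \frac{1}{N}\sum_{(i,j)} \frac{1}
#'   {1 + \exp[\beta (r_{ij}(X) - \lambda r^0_{ij})]}}
#' with smoothing \code{beta} (default 5 per Angstrom) and contact-
#' fluctuation factor \code{lambda} (default 1.5).
#'
#' @param frame coordinate matrix.
#' @param pairs data.frame from [nativePairsQ()] (columns i, j, r0).
#' @param beta switching steepness (1/Angstrom).
#' @param lambda fluctuation allowance.
#' @return Q in (0, 1].
#' @export
qFraction <- function(frame, pairs, beta = 5, lambda = 1.5) {
  stopifnot(nrow(pairs) > 0)
  r <- .pair_dist(frame, pairs$i, pairs$j)
  mean(1 / (1 + exp(beta * (r - lambda * pairs$r0))))
}

#' Contact pairs for the ratchet collective variable
#'
#' All heavy-atom pairs with atom-index separation greater than
#' \code{minIndexSep} (35; boundary exclusive) and native distance up to and
#' including \code{cutoff} (12 Angstrom, i.e. 1.2 nm).
#'
#' @param native native coordinates.
#' @param atoms topology data.frame.
#' @param cutoff native-distance cutoff (Angstrom, inclusive).
#' @param minIndexSep atom-index separation; pairs with \code{j - i >
#'   minIndexSep} are kept.
#' @param r0_contact contact-function reference distance (Angstrom) used to
#'   precompute the native contact-map entries.
#' @return data.frame with columns \code{i}, \code{j}, \code{r0} (native
#'   distance) and \code{cnat} (native contact-function value).
#' @export
rmdPairs <- function(native, atoms, cutoff = 12.0, minIndexSep = 35,
                     r0_contact = 7.5) {
  heavy <- which(!(atoms$element %in% c("H", "D")))
  cp <- .candidate_pairs(native, heavy, cutoff)
  # positions within the heavy-atom index list define the separation rule
  hpos <- match(seq_len(nrow(atoms)), heavy)
  keep <- abs(hpos[cp$j] - hpos[cp$i]) > minIndexSep
  out <- cp[keep, , drop = FALSE]
  out$cnat <- contactFunction(out$r0, r0_contact)
  rownames(out) <- NULL
  out
}

#' Rational contact switching function
#'
#' \deqn{C(r) = \frac{1 - (r/r_0)^6}{1 - (r/r_0)^{10}}}
#' evaluated in the factored geometric-series form
#' \eqn{(\sum_{k<6} x^k)/(\sum_{k<10} x^k)}, which equals the rational form
#' for \eqn{x \neq 1} and its limit 0.6 at \eqn{x = 1}; strictly decreasing
#' in r, with C(0) = 1.
#'
#' @param r distance(s), Angstrom.
#' @param r0 reference distance (default 7.5 Angstrom, i.e. 0.75 nm).
#' @return contact value(s) in (0, 1].
#' @examples
#' contactFunction(7.5)          # exactly 0.6
#' contactFunction(12, 7.5)      # ~0.1448
#' @export
contactFunction <- function(r, r0 = 7.5) {
  stopifnot(all(r >= 0), r0 > 0)
  contact_switch_vec_cpp(as.numeric(r), r0)
}

#' Ratchet collective variable: squared contact-map distance to native
#'
#' \deqn{CV(X) = \sum_{(i,j)} [C_{ij}(X) - C_{ij}(X_{native})]^2}
#' over the [rmdPairs()] list; zero iff every pair reproduces its native
#' contact value.
#'
#' @param frame coordinate matrix.
#' @param pairs data.frame from [rmdPairs()].
#' @param r0_contact contact-function reference distance.
#' @return non-negative scalar.
#' @export
rmdCv <- function(frame, pairs, r0_contact = 7.5) {
  r <- .pair_dist(frame, pairs$i, pairs$j)
  sum((contactFunction(r, r0_contact) - pairs$cnat)^2)
}

#' Ratchet-and-pawl bias energy and force prefactor
#'
#' The history-dependent bias is treated as a potential:
#' \deqn{V = \kappa/2 (\rho - \rho_m)^2 \quad (\rho > \rho_m), \qquad 0
#' \quad (\rho \le \rho_m)}
#' with \eqn{\rho = (CV - CV_{target})^2} and \eqn{\rho_m} the running
#' minimum of \eqn{\rho}. Cartesian forces follow by the chain rule through
#' the collective variable; the scalar prefactor on \eqn{\nabla\rho} is
#' \eqn{-\kappa(\rho - \rho_m)}. The bias vanishes whenever the system
#' progresses (\eqn{\rho \le \rho_m}).
#'
#' @param rho current squared distance from the CV target.
#' @param rho_min running minimum of rho.
#' @param kappa force constant (>= 0).
#' @return list with \code{energy} and \code{force_scale} (the multiplier of
#'   the CV gradient, i.e. \eqn{-\kappa(\rho-\rho_m)}; 0 on the pawl branch).
#' @export
rmdBias <- function(rho, rho_min, kappa) {
  stopifnot(kappa >= 0)
  active <- rho > rho_min
  list(energy = ifelse(active, kappa / 2 * (rho - rho_min)^2, 0),
       force_scale = ifelse(active, -kappa * (rho - rho_min), 0))
}

#' Residue-residue contact map
#'
#' Two residues are in contact when any heavy-atom pair is closer than
#' \code{cutoff} (5.0 Angstrom); the map is symmetric with a unit diagonal.
#'
#' @param frame coordinate matrix.
#' @param atoms topology data.frame.
#' @param cutoff heavy-atom distance cutoff (Angstrom, exclusive).
#' @return symmetric logical matrix, residues in order of first appearance.
#' @export
contactMap <- function(frame, atoms, cutoff = 5.0) {
  heavy <- which(!(atoms$element %in% c("H", "D")))
  res <- unique(atoms$resid)
  ri <- match(atoms$resid[heavy], res)
  dm <- as.matrix(stats::dist(frame[heavy, , drop = FALSE]))
  n <- length(res)
  out <- matrix(FALSE, n, n, dimnames = list(res, res))
  close <- which(dm < cutoff, arr.ind = TRUE)
  out[cbind(ri[close[, 1]], ri[close[, 2]])] <- TRUE
  diag(out) <- TRUE
  out
}

#' Ensemble contact probability and contact-map differences
#'
#' \code{ensembleContactProbability} averages per-frame contact maps over an
#' ensemble; \code{contactDifference} subtracts two probability (or boolean)
#' maps, giving values in [-1, 1].
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param cutoff contact cutoff (Angstrom).
#' @return numeric matrix of contact probabilities in [0, 1].
#' @export
ensembleContactProbability <- function(ensemble, cutoff = 5.0) {
  nf <- nFrames(ensemble)
  acc <- NULL
  for (f in seq_len(nf)) {
    m <- contactMap(getFrame(ensemble, f), ensemble@atoms, cutoff)
    acc <- if (is.null(acc)) m * 1 else acc + m
  }
  acc / nf
}

#' @rdname ensembleContactProbability
#' @param A,B contact probability maps of identical dimensions.
#' @export
contactDifference <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  A * 1 - B * 1
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are superposed onto the ensemble mean structure (the mean is
#' re-computed once after an initial superposition onto the first frame),
#' then \code{RMSF_i = sqrt(mean_f |x_i(f) - xbar_i|^2)}.
#'
#' @param ensemble a [StructureEnsemble-class] with at least 2 frames.
#' @param selection atom indices used for superposition and reported (default
#'   CA atoms; falls back to all atoms when no CA present).
#' @return named numeric vector of RMSF values (Angstrom) for the selection.
#' @export
rmsf <- function(ensemble, selection = NULL) {
  nf <- nFrames(ensemble)
  if (nf < 2) stop("RMSF needs at least 2 frames")
  if (is.null(selection)) {
    selection <- caIndices(ensemble)
    if (!length(selection)) selection <- seq_len(nAtoms(ensemble))
  }
  ref <- getFrame(ensemble, 1)
  aligned <- lapply(seq_len(nf), function(f)
    kabschSuperpose(getFrame(ensemble, f), ref, selection)$coords)
  mean1 <- Reduce(`+`, aligned) / nf
  aligned <- lapply(aligned, function(x)
    kabschSuperpose(x, mean1, selection)$coords)
  xbar <- Reduce(`+`, aligned) / nf
  msf <- Reduce(`+`, lapply(aligned, function(x)
    rowSums((x - xbar)^2))) / nf
  out <- sqrt(msf[selection])
  names(out) <- ensemble@atoms$resid[selection]
  out
}

#' Radius of gyration
#'
#' Mass-weighted: \code{sqrt(sum(m |x - x_com|^2) / sum(m))}.
#'
#' @param frame coordinate matrix (>= 2 atoms).
#' @param masses atomic masses; default unit masses.
#' @return Rg in Angstrom.
#' @export
radiusOfGyration <- function(frame, masses = NULL) {
  if (nrow(frame) < 2) stop("need at least 2 atoms")
  if (is.null(masses)) masses <- rep(1, nrow(frame))
  com <- colSums(frame * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(frame, 2, com)^2)) / sum(masses))
}
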
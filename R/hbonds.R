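#' @include structure.R geometry.R
NULL

.angle_deg <- function(v1, v2) {
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

#' Detect conventional hydrogen bonds
#'
#' A donor-H...acceptor triple is a hydrogen bond when the H...acceptor
#' distance is below \code{distCutoff} (2.5 Angstrom) and the
#' donor-H...acceptor angle exceeds \code{angleCutoff} (120 degrees).
#' Acceptors default to all N and O atoms outside the donor residue's amide
#' group.
#'
#' @param frame coordinate matrix with explicit hydrogen positions.
#' @param atoms topology data.frame.
#' @param donors data.frame with columns \code{n}, \code{h} (atom indices);
#'   default the backbone amides from [amideGroups()]. An amide nitrogen
#'   without a proton raises an error naming the residue.
#' @param acceptors integer vector of acceptor atom indices; default all
#'   N/O atoms.
#' @param distCutoff H...acceptor cutoff (Angstrom).
#' @param angleCutoff donor-H...acceptor angle threshold (degrees).
#' @return data.frame: donor/H/acceptor indices, donor and acceptor residue,
#'   distance and angle; zero rows when nothing is found.
#' @export
detectHydrogenBonds <- function(frame, atoms, donors = NULL, acceptors = NULL,
                                distCutoff = 2.5, angleCutoff = 120) {
  if (is.null(donors)) {
    ens <- structureEnsemble(atoms, frame)
    donors <- amideGroups(ens)
    # amide N present but proton missing -> name the residue
    at <- atoms
    for (r in setdiff(unique(at$resid), c(at$resid[1]))) {
      rows <- which(at$resid == r)
      if (at$resname[rows[1]] == "PRO") next
      has_n <- any(at$name[rows] == "N")
      has_h <- any(at$name[rows] %in% c("H", "HN", "H1", "HT1"))
      if (has_n && !has_h)
        stop("residue ", at$resname[rows[1]], r,
             " has an amide nitrogen but no amide proton")
    }
  }
  if (is.null(acceptors)) acceptors <- which(atoms$element %in% c("N", "O"))
  out <- list()
  for (k in seq_len(nrow(donors))) {
    ni <- donors$n[k]; hi <- donors$h[k]
    acc <- setdiff(acceptors, c(ni, hi))
    if (!length(acc)) next
    dv <- sweep(frame[acc, , drop = FALSE], 2, frame[hi, ])
    d <- sqrt(rowSums(dv^2))
    cand <- which(d < distCutoff)
    for (a in cand) {
      ang <- .angle_deg(frame[ni, ] - frame[hi, ],
                        frame[acc[a], ] - frame[hi, ])
      if (ang > angleCutoff)
        out[[length(out) + 1]] <- data.frame(
          donor = ni, h = hi, acceptor = acc[a],
          donor_resid = atoms$resid[ni], acceptor_resid = atoms$resid[acc[a]],
          dist = d[a], angle = ang)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), h = integer(), acceptor = integer(),
                      donor_resid = integer(), acceptor_resid = integer(),
                      dist = numeric(), angle = numeric()))
  do.call(rbind, out)
}

#' Detect amide-pi hydrogen bonds
#'
#' An amide N-H interacts with an aromatic ring face when all four criteria
#' hold: (1) the H to ring center-of-mass distance is below 4.5 Angstrom;
#' (2) the angle between the ring normal and the H-to-COM vector, taken in
#' the acute convention min(theta, 180 - theta), is below 54.7 degrees (the
#' amide points at the ring face); (3) the N-H...COM angle exceeds 120
#' degrees (donor directionality); (4) the proton is not engaged in a
#' conventional hydrogen bond to any non-aromatic acceptor. Trp contributes
#' its 5- and 6-membered rings independently; an amide counts as interacting
#' when any ring passes.
#'
#' @param frame coordinate matrix with protons.
#' @param atoms topology data.frame.
#' @param rings ring list from [buildRings()]; built from the frame when
#'   NULL.
#' @param amides donor table as in [detectHydrogenBonds()].
#' @param includeHis include His rings when building rings.
#' @param distCutoff,normalAngleCutoff,nhAngleCutoff the three geometric
#'   thresholds.
#' @return data.frame: amide residue, ring residue/type/label, distance and
#'   the two angles, one row per passing amide-ring combination.
#' @export
detectAmidePi <- function(frame, atoms, rings = NULL, amides = NULL,
                          includeHis = TRUE, distCutoff = 4.5,
                          normalAngleCutoff = 54.7, nhAngleCutoff = 120) {
  ens <- structureEnsemble(atoms, frame)
  if (is.null(rings)) rings <- buildRings(ens, 1, includeHis = includeHis)
  if (is.null(amides)) amides <- amideGroups(ens)
  if (!length(rings) || !nrow(amides))
    return(data.frame(amide_resid = integer(), ring_resid = integer(),
                      ring_resname = character(), ring_label = character(),
                      dist = numeric(), normal_angle = numeric(),
                      nh_angle = numeric()))
  ring_atoms <- unlist(lapply(rings, `[[`, "members"))
  nonarom <- setdiff(which(atoms$element %in% c("N", "O")), ring_atoms)
  out <- list()
  for (k in seq_len(nrow(amides))) {
    ni <- amides$n[k]; hi <- amides$h[k]
    # criterion 4: free of conventional hydrogen bonds to non-aromatic
    # acceptors
    hb <- detectHydrogenBonds(frame, atoms,
                              donors = amides[k, , drop = FALSE],
                              acceptors = nonarom)
    if (nrow(hb)) next
    for (rg in rings) {
      if (rg$resid == amides$resid[k]) next
      v <- rg$com - frame[hi, ]
      d <- sqrt(sum(v^2))
      if (d >= distCutoff) next
      na <- .angle_deg(rg$normal, v)
      na <- min(na, 180 - na)
      if (na >= normalAngleCutoff) next
      nh <- .angle_deg(frame[ni, ] - frame[hi, ], rg$com - frame[hi, ])
      if (nh <= nhAngleCutoff) next
      out[[length(out) + 1]] <- data.frame(
        amide_resid = amides$resid[k], ring_resid = rg$resid,
        ring_resname = rg$resname, ring_label = rg$label, dist = d,
        normal_angle = na, nh_angle = nh)
    }
  }
  if (!length(out))
    return(data.frame(amide_resid = integer(), ring_resid = integer(),
                      ring_resname = character(), ring_label = character(),
                      dist = numeric(), normal_angle = numeric(),
                      nh_angle = numeric()))
  do.call(rbind, out)
}

#' Ensemble frequencies of amide-pi interactions
#'
#' Per-amide and per-aromatic-residue-type interaction frequencies over an
#' ensemble: the fraction of frames in which the amide (or any ring of the
#' residue type) participates in at least one amide-pi hydrogen bond.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param ... passed to [detectAmidePi()].
#' @return list with \code{perAmide} (data.frame resid, frequency) and
#'   \code{perRingType} (data.frame resname, frequency).
#' @export
ensembleAmidePiProbability <- function(ensemble, ...) {
  nf <- nFrames(ensemble)
  amides <- amideGroups(ensemble)
  ring_types <- c("TRP", "TYR", "PHE", "HIS")
  amide_hits <- setNames(numeric(nrow(amides)), amides$resid)
  ring_hits <- setNames(numeric(length(ring_types)), ring_types)
  for (f in seq_len(nf)) {
    det <- detectAmidePi(getFrame(ensemble, f), ensemble@atoms, ...)
    if (nrow(det)) {
      hit_res <- unique(det$amide_resid)
      amide_hits[as.character(hit_res)] <-
        amide_hits[as.character(hit_res)] + 1
      hit_type <- unique(det$ring_resname)
      ring_hits[hit_type] <- ring_hits[hit_type] + 1
    }
  }
  list(perAmide = data.frame(resid = amides$resid,
                             frequency = as.numeric(amide_hits) / nf),
       perRingType = data.frame(resname = ring_types,
                                frequency = as.numeric(ring_hits) / nf))
}
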
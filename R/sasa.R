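#' @include structure.R
NULL

# van der Waals radii (Angstrom) by element; unknown elements fall back on
# carbon
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Classic sphere-point algorithm: \code{nPoints} quasi-uniform points
#' (golden-spiral construction) are placed on each atom's solvent-expanded
#' sphere (vdW radius + probe) and tested against all neighbouring spheres;
#' the accessible fraction times the sphere area gives the per-atom SASA.
#'
#' @param frame coordinate matrix (Angstrom).
#' @param elements element symbol per atom (used for vdW radii); or a
#'   numeric vector of radii.
#' @param probe probe radius (default 1.4 Angstrom, water).
#' @param nPoints sphere points per atom (default 960).
#' @return list with \code{atom} (per-atom SASA) and \code{total}, in
#'   Angstrom^2.
#' @export
sasaShrakeRupley <- function(frame, elements, probe = 1.4, nPoints = 960) {
  n <- nrow(frame)
  radii <- if (is.numeric(elements)) elements
           else {
             r <- .vdw_radii[elements]
             r[is.na(r)] <- .vdw_radii[["C"]]
             unname(r)
           }
  stopifnot(length(radii) == n)
  # golden-spiral sphere points
  k <- seq_len(nPoints) - 0.5
  phi <- acos(1 - 2 * k / nPoints)
  theta <- pi * (1 + sqrt(5)) * k
  sp <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  rs <- radii + probe
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(frame, 2, frame[i, ])^2)
    nb <- which(d2 < (rs[i] + rs)^2 & seq_len(n) != i)
    pts <- sweep(sp * rs[i], 2, frame[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(pts[acc, , drop = FALSE], 2, frame[j, ])^2)
      acc[acc] <- dj > rs[j]^2
    }
    atom_sasa[i] <- 4 * pi * rs[i]^2 * sum(acc) / nPoints
  }
  list(atom = atom_sasa, total = sum(atom_sasa))
}
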
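#' @include geometry.R
NULL

#' Pairwise superposed RMSD matrix
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param selection atom indices (default CA, falling back to all atoms).
#' @return symmetric nframes x nframes matrix (Angstrom).
#' @export
pairwiseRmsd <- function(ensemble, selection = NULL) {
  if (is.null(selection)) {
    selection <- caIndices(ensemble)
    if (!length(selection)) selection <- seq_len(nAtoms(ensemble))
  }
  nf <- nFrames(ensemble)
  frames <- lapply(seq_len(nf), function(f)
    getFrame(ensemble, f)[selection, , drop = FALSE])
  out <- matrix(0, nf, nf)
  for (a in seq_len(nf - 1)) for (b in (a + 1):nf) {
    out[a, b] <- out[b, a] <- kabschSuperpose(frames[[a]], frames[[b]])$rmsd
  }
  out
}

#' GROMOS conformational clustering
#'
#' Greedy neighbor-count clustering: the frame with the most neighbours
#' within \code{cutoff} RMSD becomes a cluster center, its neighbourhood is
#' removed, and the procedure repeats until every frame is assigned. Ties in
#' the neighbour count are broken by the lowest frame index, making the
#' output deterministic. Clusters partition the ensemble and the first
#' cluster is the largest.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param selection atom indices for the RMSD (default CA).
#' @param cutoff neighbourhood RMSD cutoff in Angstrom (default 5).
#' @return list of clusters, each with \code{center} (frame index) and
#'   \code{members} (frame indices, center included).
#' @export
clusterGromos <- function(ensemble, selection = NULL, cutoff = 5.0) {
  nf <- nFrames(ensemble)
  if (nf == 1) return(list(list(center = 1L, members = 1L)))
  dm <- pairwiseRmsd(ensemble, selection)
  remaining <- seq_len(nf)
  clusters <- list()
  while (length(remaining)) {
    counts <- vapply(remaining, function(i)
      sum(dm[i, remaining] <= cutoff), integer(1))
    center <- remaining[which.max(counts)]  # which.max: lowest index on ties
    members <- remaining[dm[center, remaining] <= cutoff]
    clusters[[length(clusters) + 1]] <- list(center = center,
                                             members = sort(members))
    remaining <- setdiff(remaining, members)
  }
  clusters
}

# separable Gaussian smoothing with a 4-sigma truncated kernel; borders are
# renormalized over the in-range kernel mass
.gaussian_smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  w <- ceiling(4 * sigma)
  k <- exp(-(seq(-w, w))^2 / (2 * sigma^2))
  smooth1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - w); hi <- min(n, i + w)
      kk <- k[(lo - i + w + 1):(hi - i + w + 1)]
      out[i] <- sum(v[lo:hi] * kk) / sum(kk)
    }
    out
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

#' Free-energy landscape over two collective variables
#'
#' Bins the samples on a 2-D grid, smooths the histogram counts with a
#' Gaussian filter (sigma in bin units) before taking the logarithm, and
#' converts to free energy \code{F = -RT log(H / max(H))} in kJ/mol, so the
#' global minimum is exactly 0. Bins with no smoothed density are +Inf.
#'
#' @param cv1,cv2 numeric sample vectors (e.g. CA-RMSD and Q); >= 100
#'   samples.
#' @param temperatureK temperature for RT (default 350 K).
#' @param bins number of bins per axis (length 1 or 2).
#' @param sigma Gaussian smoothing width in bins (default 2).
#' @param cvNames axis names.
#' @return a [Landscape-class].
#' @export
freeEnergyLandscape <- function(cv1, cv2, temperatureK = 350, bins = 60,
                                sigma = 2, cvNames = c("rmsd", "Q")) {
  stopifnot(length(cv1) == length(cv2))
  if (length(cv1) < 100) stop("need at least 100 samples")
  bins <- rep(bins, length.out = 2)
  xb <- seq(min(cv1), max(cv1), length.out = bins[1] + 1)
  yb <- seq(min(cv2), max(cv2), length.out = bins[2] + 1)
  xi <- pmin(pmax(findInterval(cv1, xb, all.inside = TRUE), 1), bins[1])
  yi <- pmin(pmax(findInterval(cv2, yb, all.inside = TRUE), 1), bins[2])
  H <- matrix(0, bins[1], bins[2])
  for (k in seq_along(xi)) H[xi[k], yi[k]] <- H[xi[k], yi[k]] + 1
  if (sum(H) == 0) stop("empty histogram")
  Hs <- .gaussian_smooth2d(H, sigma)
  RT <- 0.0083145 * temperatureK
  f <- -RT * log(Hs / max(Hs))
  f[Hs <= 0] <- Inf
  new("Landscape", xmids = (xb[-1] + xb[-length(xb)]) / 2,
      ymids = (yb[-1] + yb[-length(yb)]) / 2, free = f,
      temperatureK = temperatureK, sigma = sigma, cvNames = cvNames)
}

# 4-connected component labelling of a logical matrix
.label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      i <- (v - 1) %% nr + 1; j <- (v - 1) %/% nr + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- c(queue, (jj - 1) * nr + ii)
        }
      }
    }
  }
  lab
}

#' Extract non-native basins from a landscape
#'
#' Basins are the 4-connected components of \code{{F < threshold}} after
#' excluding the component that contains the global minimum (the native
#' basin). Each basin is reported with its minimum free energy and location.
#'
#' @param landscape a [Landscape-class].
#' @param threshold free-energy threshold in kJ/mol (default 11).
#' @return list with \code{native} (mask of the native component) and
#'   \code{basins}, a list of \code{mask}, \code{min} (kJ/mol),
#'   \code{at} (CV coordinates of the basin minimum).
#' @export
findBasins <- function(landscape, threshold = 11) {
  f <- landscape@free
  mask <- is.finite(f) & f < threshold
  if (!any(mask)) return(list(native = mask, basins = list()))
  lab <- .label_components(mask)
  gmin <- which(f == 0, arr.ind = TRUE)[1, ]
  native_lab <- lab[gmin[1], gmin[2]]
  basins <- list()
  for (l in setdiff(unique(lab[lab > 0]), native_lab)) {
    bm <- lab == l
    idx <- which(bm & f == min(f[bm]), arr.ind = TRUE)[1, ]
    basins[[length(basins) + 1]] <- list(
      mask = bm, min = min(f[bm]),
      at = c(landscape@xmids[idx[1]], landscape@ymids[idx[2]]))
  }
  list(native = lab == native_lab, basins = basins)
}
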
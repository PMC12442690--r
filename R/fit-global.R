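#' @include AllClasses.R simulate.R
NULL

topologyStates <- function(topology) {
  switch(topology,
         two_state = c("N", "D"),
         "N-I-D" = , "N-D-I" = , "I-N-D" = , triangular = c("N", "I", "D"),
         stop("unknown topology: ", topology))
}

topologyEdges <- function(topology) {
  switch(topology,
         two_state = list(c("N", "D")),
         "N-I-D" = list(c("N", "I"), c("I", "D")),
         "N-D-I" = list(c("N", "D"), c("D", "I")),
         "I-N-D" = list(c("I", "N"), c("N", "D")),
         triangular = list(c("N", "I"), c("I", "D"), c("N", "D")),
         stop("unknown topology: ", topology))
}

edgeName <- function(edge) {
  # canonical order N, I, D so kex_IN becomes kex_NI
  ord <- c(N = 1, I = 2, D = 3)
  e <- edge[order(ord[edge])]
  paste0("kex_", e[1], e[2])
}

.softmax_pops <- function(u, labels) {
  w <- c(1, exp(u))
  p <- w / sum(w)
  names(p) <- labels
  p
}

.buildK <- function(p, edges, kex) {
  S <- length(p)
  K <- matrix(0, S, S)
  for (e in seq_along(edges)) {
    i <- match(edges[[e]][1], names(p))
    j <- match(edges[[e]][2], names(p))
    ps <- p[i] + p[j]
    if (ps > 0) {
      K[j, i] <- K[j, i] + kex[e] * p[j] / ps
      K[i, j] <- K[i, j] + kex[e] * p[i] / ps
    }
  }
  diag(K) <- -colSums(K)
  K
}

# running-mean smoother used by the dip initializer
.running_mean <- function(y, k = 3) {
  as.numeric(stats::filter(y, rep(1 / k, k), sides = 2)) -> ys
  ys[is.na(ys)] <- y[is.na(ys)]
  ys
}

# local minima of a CEST profile: returns data.frame(x, depth), deepest
# first; the depth threshold scales with the point-to-point noise so shallow
# minor-state dips near the detection limit are kept
.profile_minima <- function(x, y) {
  ys <- .running_mean(y, 3)
  base <- as.numeric(stats::quantile(ys, 0.9))
  idx <- which(diff(sign(diff(ys))) == 2) + 1
  idx <- union(idx, which.min(ys))
  depth <- base - ys[idx]
  noise <- stats::mad(diff(y)) / sqrt(2)
  keep <- depth > max(5 * noise, 0.03 * max(depth))
  d <- data.frame(x = x[idx[keep]], depth = depth[keep])
  d[order(-d$depth), , drop = FALSE]
}

# data-driven starting shifts: N from the N-observed peak position, D from
# the D-observed one, I from the deepest remaining dip across all profiles.
# Also returns fractional dip depths per state seen from the N- and
# D-observed profiles (highest B1: most complete saturation), used to seed
# the exchange rates via depth ~ k * Tex.
.init_shifts <- function(cest_profiles, states) {
  stopifnot(length(cest_profiles) >= 1)
  b1 <- vapply(cest_profiles, function(p) p@meta$B1_Hz, numeric(1))
  obs <- vapply(cest_profiles, function(p) {
    o <- p@meta$observe
    if (is.null(o) || is.na(o)) "N" else o
  }, character(1))
  pick <- function(state, strongest = FALSE) {
    i <- which(obs == state)
    if (!length(i)) i <- seq_along(cest_profiles)
    if (strongest) i[which.max(b1[i])] else i[which.min(b1[i])]
  }
  pn <- cest_profiles[[pick("N")]]
  step <- median(abs(diff(pn@data$x)))
  sep <- 5 * step
  sh <- c(N = pn@data$x[which.min(pn@data$y)])
  if ("D" %in% states) {
    # the deepest dip of the D-observed profile can be the N exchange dip
    # when N dominates; take the deepest minimum away from the N position
    pd <- cest_profiles[[pick("D")]]
    cand <- .profile_minima(pd@data$x, pd@data$y)
    cand <- cand[abs(cand$x - sh[["N"]]) > 1.5 * step, , drop = FALSE]
    sh[["D"]] <- if (nrow(cand)) cand$x[1] else sh[["N"]] + 4 * sep
  }
  if ("I" %in% states) {
    cands <- do.call(rbind, lapply(cest_profiles, function(p)
      .profile_minima(p@data$x, p@data$y)))
    cands <- cands[order(-cands$depth), , drop = FALSE]
    far <- abs(cands$x - sh[["N"]]) > sep & abs(cands$x - sh[["D"]]) > sep
    sh[["I"]] <- if (any(far)) cands$x[which(far)[1]]
                 else mean(c(sh[["N"]], sh[["D"]])) + 2 * sep
  }
  depth_from <- function(state) {
    p <- cest_profiles[[pick(state, strongest = TRUE)]]
    base <- as.numeric(stats::quantile(p@data$y, 0.9))
    d <- vapply(sh, function(s) {
      base - p@data$y[which.min(abs(p@data$x - s))]
    }, numeric(1))
    pmin(pmax(d / max(base, 0.05), 0.005), 0.95)
  }
  list(shifts = sh[states], Tex = pn@meta$Tex_s,
       depthN = depth_from("N"),
       depthD = if ("D" %in% obs) depth_from("D") else NULL)
}

# Build the parameter spec, grouping structure and initial values for one
# global fit. Profiles sharing (residue, nucleus, temperature, experiment,
# field, B1/Tex or Tcp and x grid) share one Bloch-McConnell propagation.
.prepare_fit <- function(data, topology, shareShifts = TRUE) {
  stopifnot(is(data, "ProfileDataset"))
  prof <- data@profiles
  if (!length(prof)) stop("dataset is empty")
  states <- topologyStates(topology)
  edges <- topologyEdges(topology)

  tkeys <- sort(unique(vapply(prof, function(p) p@temperatureK, numeric(1))))
  tlab <- sprintf("%.2fK", tkeys)
  multiT <- length(tkeys) > 1

  lockey <- function(p) {
    k <- paste(p@residue, p@nucleus, sep = "_")
    if (!shareShifts && multiT) k <- paste0(k, "_", sprintf("%.2fK", p@temperatureK))
    k
  }
  lkeys <- unique(vapply(prof, lockey, character(1)))

  # --- local starting values (CEST dip positions, depths, baselines) -------
  locinfo <- list()
  for (lk in lkeys) {
    sel <- prof[vapply(prof, function(p) lockey(p) == lk, logical(1))]
    cest <- sel[vapply(sel, function(p) p@experiment == "cest", logical(1))]
    nuc <- sel[[1]]@nucleus
    # typical amide longitudinal rates; the CEST baseline carries little R1
    # information (magnetization starts at equilibrium), so a generic start
    # is as good as any
    r1_0 <- if (nuc == "1H") 2.0 else 1.2
    if (length(cest)) {
      ini <- .init_shifts(cest, states)
      xr <- range(unlist(lapply(cest, function(p) p@data$x)))
      locinfo[[lk]] <- list(sh0 = ini$shifts, lo = xr[1] - 1, hi = xr[2] + 1,
                            r1_0 = r1_0, nuc = nuc, depthN = ini$depthN,
                            depthD = ini$depthD, Tex = ini$Tex)
    } else {
      locinfo[[lk]] <- list(sh0 = setNames(rep(0, length(states)), states),
                            lo = -1000, hi = 1000, r1_0 = r1_0, nuc = nuc,
                            depthN = NULL, depthD = NULL, Tex = NA)
    }
  }

  # starting populations: the ratio of the exchange-dip depths seen from
  # the two observed peaks estimates p_N/p_D (saturation efficiency
  # cancels); the minor intermediate starts near the CEST detection floor
  pD0 <- unlist(lapply(locinfo, function(li) {
    if (is.null(li$depthN) || is.null(li$depthD) || !"D" %in% states)
      return(NULL)
    dN <- li$depthN[["D"]]   # D dip seen from the N peak ~ k(N->D)
    dD <- li$depthD[["N"]]   # N dip seen from the D peak ~ k(D->N)
    dN / (dN + dD)
  }))
  pD0 <- if (length(pD0)) min(max(median(pD0), 0.02), 0.95) else 0.4
  p0 <- if ("I" %in% states) {
    c(N = (1 - pD0) * 0.995 / (1 + 0.005), I = 0.005, D = pD0)
  } else c(N = 1 - pD0, D = pD0)
  p0 <- p0 / sum(p0)
  # exchange-rate starts from saturation-transfer dip depths: depth ~ k * Tex
  kex0 <- function(edge) {
    ests <- unlist(lapply(locinfo, function(li) {
      if (is.null(li$depthN) || is.na(li$Tex)) return(NULL)
      if ("N" %in% edge) {
        minor <- setdiff(edge, "N")
        d <- li$depthN[[minor]]
        d / li$Tex * (p0[["N"]] + p0[[minor]]) / p0[[minor]]
      } else if (!is.null(li$depthD)) {
        d <- li$depthD[["I"]]
        d / li$Tex * (p0[["D"]] + p0[["I"]]) / p0[["I"]]
      } else NULL
    }))
    if (!length(ests)) 50 else min(max(median(ests), 1), 1500)
  }

  # --- parameter spec -------------------------------------------------------
  spec <- list()
  addp <- function(name, kind, init, lower, upper, tkey = "", lkey = "",
                   state = "", edge = "") {
    spec[[length(spec) + 1]] <<- data.frame(
      name = name, kind = kind, init = init, lower = lower, upper = upper,
      tkey = tkey, lkey = lkey, state = state, edge = edge,
      stringsAsFactors = FALSE)
  }

  for (ti in seq_along(tkeys)) {
    suff <- if (multiT) paste0("_", tlab[ti]) else ""
    for (s in states[-1]) {
      addp(paste0("p_", s, suff), "pop", log(p0[[s]] / p0[["N"]]), -16, 6,
           tkey = tlab[ti], state = s)
    }
    for (e in edges) {
      addp(paste0(edgeName(e), suff), "kex", log10(kex0(e)), -1, 3.3,
           tkey = tlab[ti], edge = edgeName(e))
    }
  }

  for (lk in lkeys) {
    li <- locinfo[[lk]]
    r2_0 <- if (li$nuc == "1H") 15 else 10
    for (s in states)
      addp(paste0("dw_", lk, "_", s), "shift", li$sh0[[s]], li$lo, li$hi,
           lkey = lk, state = s)
    addp(paste0("R1_", lk), "logR", log10(li$r1_0), -1, 1, lkey = lk)
    for (s in states)
      addp(paste0("R2_", lk, "_", s), "logR", log10(r2_0), -0.3, 2.5,
           lkey = lk, state = s)
  }
  spec <- do.call(rbind, spec)

  # --- propagation groups ---------------------------------------------------
  gkey <- function(p) paste(p@experiment, lockey(p),
                            sprintf("%.2fK", p@temperatureK), p@B0_MHz_1H,
                            if (p@experiment == "cest")
                              paste(p@meta$B1_Hz, p@meta$Tex_s,
                                    length(p@data$x), p@data$x[1])
                            else p@meta$Tcp_s,
                            sep = "|")
  keys <- vapply(prof, gkey, character(1))
  groups <- list()
  row0 <- 0L
  for (k in unique(keys)) {
    sel <- which(keys == k)
    p1 <- prof[[sel[1]]]
    entries <- list()
    for (i in sel) {
      p <- prof[[i]]
      obs <- p@meta$observe
      if (is.null(obs) || is.na(obs)) obs <- states[1]
      oi <- match(obs, states)
      if (is.na(oi)) stop("profile observes unknown state ", obs)
      n <- nrow(p@data)
      entries[[length(entries) + 1]] <-
        list(obs = oi, y = p@data$y, sigma = p@data$sigma,
             rows = seq.int(row0 + 1L, row0 + n), profile = i)
      row0 <- row0 + n
    }
    groups[[length(groups) + 1]] <- list(
      type = p1@experiment, nucleus = p1@nucleus, B0 = p1@B0_MHz_1H,
      tkey = sprintf("%.2fK", p1@temperatureK), lkey = lockey(p1),
      B1 = p1@meta$B1_Hz, Tex = p1@meta$Tex_s, Tcp = p1@meta$Tcp_s,
      x = p1@data$x, entries = entries)
  }

  list(spec = spec, groups = groups, states = states, edges = edges,
       tlab = tlab, multiT = multiT, npoints = row0)
}

.decode_params <- function(par, prep) {
  spec <- prep$spec
  states <- prep$states
  out <- list(pops = list(), K = list(), kex = list(), loc = list())
  for (tl in prep$tlab) {
    u <- par[spec$kind == "pop" & spec$tkey == tl]
    p <- .softmax_pops(u, states)
    kx <- 10^par[spec$kind == "kex" & spec$tkey == tl]
    out$pops[[tl]] <- p
    out$K[[tl]] <- .buildK(p, prep$edges, kx)
    out$kex[[tl]] <- setNames(kx, spec$name[spec$kind == "kex" & spec$tkey == tl])
  }
  for (lk in unique(spec$lkey[spec$lkey != ""])) {
    rows <- spec$lkey == lk
    sh <- par[rows & spec$kind == "shift"]
    names(sh) <- spec$state[rows & spec$kind == "shift"]
    r1 <- 10^par[rows & spec$kind == "logR" & spec$state == ""]
    r2 <- 10^par[rows & spec$kind == "logR" & spec$state != ""]
    names(r2) <- spec$state[rows & spec$kind == "logR" & spec$state != ""]
    out$loc[[lk]] <- list(shifts = sh[states], R1 = r1, R2 = r2[states])
  }
  out
}

.fit_residuals <- function(par, prep) {
  dec <- .decode_params(par, prep)
  res <- numeric(prep$npoints)
  S <- length(prep$states)
  for (g in prep$groups) {
    p <- dec$pops[[g$tkey]]
    K <- dec$K[[g$tkey]]
    loc <- dec$loc[[g$lkey]]
    M <- if (g$type == "cest") {
      cestRatios(unname(p), rep(loc$R1, S), unname(loc$R2), unname(loc$shifts),
                 g$nucleus, g$B0, g$x, g$B1, g$Tex, K)
    } else if (g$type == "cpmg") {
      cpmgRates(unname(p), unname(loc$R2), unname(loc$shifts), g$nucleus,
                g$B0, g$x, g$Tcp, K)
    } else stop("unsupported experiment in global fit: ", g$type)
    for (e in g$entries) res[e$rows] <- (e$y - M[e$obs, ]) / e$sigma
  }
  res
}

# Apply natural-scale starting values (by parameter name) onto the
# transformed init column of a parameter spec. Population entries are
# converted jointly per temperature (softmax inverse, reference state first).
.apply_init <- function(prep, init) {
  spec <- prep$spec
  states <- prep$states
  for (tl in prep$tlab) {
    suff <- if (prep$multiT) paste0("_", tl) else ""
    rows <- which(spec$kind == "pop" & spec$tkey == tl)
    pnames <- paste0("p_", states, suff)
    if (any(pnames %in% names(init))) {
      p <- vapply(states, function(s) {
        nm <- paste0("p_", s, suff)
        if (nm %in% names(init)) init[[nm]] else NA_real_
      }, numeric(1))
      pN <- if (is.na(p[1])) max(1 - sum(p[-1], na.rm = TRUE), 1e-6) else p[1]
      for (r in rows) {
        s <- spec$state[r]
        ps <- p[match(s, states)]
        if (!is.na(ps))
          spec$init[r] <- log(max(ps, 1e-8) / max(pN, 1e-8))
      }
    }
  }
  for (r in seq_len(nrow(spec))) {
    nm <- spec$name[r]
    if (!nm %in% names(init) || spec$kind[r] == "pop") next
    v <- init[[nm]]
    spec$init[r] <- switch(spec$kind[r],
                           kex = log10(max(v, 1e-3)),
                           logR = log10(max(v, 1e-3)),
                           shift = v)
  }
  spec$init <- pmin(pmax(spec$init, spec$lower), spec$upper)
  prep$spec <- spec
  prep
}

# Two-state prefit supplying N/D starting values for the three-state fits:
# shifts, relaxation rates, p_D and (where the topology has an N-D edge) the
# N-D exchange rate carry over; the intermediate keeps its dip-derived shift
# and a detection-floor population.
.staged_init <- function(data, prep, shareShifts, maxit) {
  pre <- tryCatch(
    globalFit(data, "two_state", nstarts = 1, shareShifts = shareShifts,
              maxit = maxit, computeSd = FALSE, stage = FALSE),
    error = function(e) NULL)
  if (is.null(pre)) return(prep)
  vals <- setNames(pre@parameters$value, pre@parameters$name)
  # seed the intermediate R2 with the native-state value
  r2n <- grep("^R2_.*_N$", names(vals), value = TRUE)
  extra <- setNames(vals[r2n], sub("_N$", "_I", r2n))
  .apply_init(prep, c(vals, extra))
}

.finite_diff_jacobian <- function(f, par, eps = 1e-6) {
  f0 <- f(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - f0) / h
  }
  J
}

# natural-scale parameter vector for reporting
.natural_params <- function(par, prep) {
  dec <- .decode_params(par, prep)
  out <- c()
  for (tl in prep$tlab) {
    suff <- if (prep$multiT) paste0("_", tl) else ""
    p <- dec$pops[[tl]]
    out <- c(out, setNames(as.numeric(p), paste0("p_", names(p), suff)))
    out <- c(out, dec$kex[[tl]])
  }
  for (lk in names(dec$loc)) {
    l <- dec$loc[[lk]]
    out <- c(out,
             setNames(as.numeric(l$shifts), paste0("dw_", lk, "_", names(l$shifts))),
             setNames(l$R1, paste0("R1_", lk)),
             setNames(as.numeric(l$R2), paste0("R2_", lk, "_", names(l$R2))))
  }
  out
}

#' Global fit of CEST/CPMG datasets to an exchange topology
#'
#' Minimizes the sigma-weighted sum of squared residuals over every profile in
#' the dataset simultaneously with Levenberg-Marquardt
#' (\code{minpack.lm::nls.lm}). Kinetic parameters (state populations and
#' pairwise exchange rates) are global per temperature; chemical shifts and
#' relaxation rates are local per residue and nucleus (R1 shared across
#' states, R2 per state). Populations are parameterized through a softmax so
#' the simplex constraint holds by construction; rates and relaxation rates
#' are fitted on a log scale. Starting values are data-driven (CEST dip
#' positions and baselines); \code{nstarts} seeded perturbed restarts guard
#' against local minima, tie-broken by lowest chi-square.
#'
#' @param data a [ProfileDataset-class].
#' @param topology one of "two_state", "N-I-D", "N-D-I", "I-N-D",
#'   "triangular".
#' @param nstarts number of multistart attempts (default 5).
#' @param seed RNG seed for the multistart perturbations.
#' @param shareShifts share chemical shifts across temperatures (multi-
#'   temperature datasets only).
#' @param maxit maximum Levenberg-Marquardt iterations per start.
#' @param computeSd compute parameter standard deviations from the
#'   inverse-Hessian covariance at the optimum (adds one Jacobian
#'   evaluation).
#' @param stage for three-state topologies, run a quick two-state prefit and
#'   seed the native/denatured parameters from it (staged fitting; default
#'   TRUE). Ignored for \code{topology = "two_state"}.
#' @param init optional named vector of natural-scale starting values (or a
#'   [FitResult-class] whose parameters are used); overrides the staged
#'   prefit, useful when fitting several topologies to one dataset.
#' @return A [FitResult-class]. Parameter values are reported on the natural
#'   scale (populations as fractions, rates in s^-1, shifts in ppm).
#'   Non-convergence is flagged in the \code{convergence} slot, not raised.
#' @seealso [modelSelection()], [writeFitReport()]
#' @export
globalFit <- function(data, topology, nstarts = 5, seed = 1,
                      shareShifts = TRUE, maxit = 200, computeSd = TRUE,
                      stage = TRUE, init = NULL) {
  prep <- .prepare_fit(data, topology, shareShifts)
  npar <- nrow(prep$spec)
  if (npar >= prep$npoints)
    stop("under-determined fit: ", npar, " parameters for ", prep$npoints,
         " points")

  if (!is.null(init)) {
    if (is(init, "FitResult"))
      init <- setNames(init@parameters$value, init@parameters$name)
    if (topology != "two_state") {
      r2n <- grep("^R2_.*_N$", names(init), value = TRUE)
      inames <- sub("_N$", "_I", r2n)
      add <- !(inames %in% names(init))
      init <- c(init, setNames(init[r2n[add]], inames[add]))
    }
    prep <- .apply_init(prep, init)
  } else if (stage && topology != "two_state") {
    prep <- .staged_init(data, prep, shareShifts, maxit = min(maxit, 100))
  }

  ctrl <- minpack.lm::nls.lm.control(maxiter = maxit, maxfev = 100 * npar * 10,
                                     ftol = 1e-12, ptol = 1e-12)
  best <- NULL
  best_trace <- NULL
  for (st in seq_len(nstarts)) {
    par0 <- prep$spec$init
    if (st > 1) {
      set.seed(seed + st)
      jit <- ifelse(prep$spec$kind == "shift", rnorm(npar, 0, 0.08),
             ifelse(prep$spec$kind == "kex", rnorm(npar, 0, 0.4),
             ifelse(prep$spec$kind == "pop", rnorm(npar, 0, 0.7),
                    rnorm(npar, 0, 0.1))))
      par0 <- pmin(pmax(par0 + jit, prep$spec$lower), prep$spec$upper)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = prep$spec$lower,
                         upper = prep$spec$upper, fn = .fit_residuals,
                         prep = prep, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      best$start <- st
      best_trace <- fit$rsstrace
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")

  # bound-escape restarts: a parameter pinned at a box bound usually marks a
  # compensation minimum (e.g. a minor-state R2 absorbing a misplaced dip);
  # re-seed pinned parameters from their starting values and re-descend
  for (round in 1:2) {
    tolb <- 1e-7
    pinned <- (best$par - prep$spec$lower < tolb) |
              (prep$spec$upper - best$par < tolb)
    pinned <- pinned & !((prep$spec$init - prep$spec$lower < tolb) |
                         (prep$spec$upper - prep$spec$init < tolb))
    if (!any(pinned)) break
    par0 <- best$par
    par0[pinned] <- prep$spec$init[pinned]
    refit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = prep$spec$lower,
                         upper = prep$spec$upper, fn = .fit_residuals,
                         prep = prep, control = ctrl),
      error = function(e) NULL)
    if (is.null(refit) || refit$deviance >= best$deviance) break
    refit$start <- best$start
    best_trace <- c(best_trace, refit$rsstrace)
    best <- refit
  }

  par <- best$par
  chi2 <- best$deviance
  n <- prep$npoints
  k <- npar
  nat <- .natural_params(par, prep)

  sds <- rep(NA_real_, length(nat))
  if (computeSd) {
    J <- .finite_diff_jacobian(function(p) .fit_residuals(p, prep), par)
    JtJ <- crossprod(J)
    cov_t <- tryCatch(solve(JtJ), error = function(e)
      tryCatch(MASS_ginv(JtJ), error = function(e2) NULL))
    if (!is.null(cov_t)) {
      G <- .finite_diff_jacobian(function(p) .natural_params(p, prep), par,
                                 eps = 1e-6)
      sds <- sqrt(pmax(diag(G %*% cov_t %*% t(G)), 0))
    }
  }

  # per-profile residual summaries
  res <- .fit_residuals(par, prep)
  psum <- do.call(rbind, lapply(prep$groups, function(g) {
    do.call(rbind, lapply(g$entries, function(e) {
      data.frame(experiment = g$type, key = g$lkey,
                 observe = prep$states[e$obs], n = length(e$rows),
                 rms_weighted_residual = sqrt(mean(res[e$rows]^2)))
    }))
  }))

  new("FitResult",
      topology = topology,
      parameters = data.frame(name = names(nat), value = as.numeric(nat),
                              sd = sds, stringsAsFactors = FALSE),
      stats = list(chi2 = chi2, reduced_chi2 = chi2 / (n - k),
                   bic = chi2 + k * log(n), aic = chi2 + 2 * k,
                   n_points = n, n_params = k, profiles = psum),
      convergence = list(converged = best$info %in% 1:4,
                         info = best$info, message = best$message,
                         niter = best$niter, start = best$start,
                         rsstrace = best_trace))
}

# Moore-Penrose fallback without importing MASS
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Extract one fitted parameter value by name
#'
#' @param fit a [FitResult-class].
#' @param name parameter name as reported in \code{parameters(fit)}.
#' @return numeric value.
#' @export
fittedParameter <- function(fit, name) {
  i <- match(name, fit@parameters$name)
  if (is.na(i)) stop("no parameter named ", name)
  fit@parameters$value[i]
}

#' Rank exchange-topology fits by information criteria
#'
#' Computes the Gaussian-likelihood model-selection statistics with constant
#' terms dropped: \code{BIC = chi2 + k log(n)}, \code{AIC = chi2 + 2 k}, and
#' returns the results sorted by BIC (stable sort: ties keep input order).
#' All fits must have been obtained on the identical dataset.
#'
#' @param results list of [FitResult-class] objects.
#' @return data.frame with one row per topology, sorted by BIC.
#' @export
modelSelection <- function(results) {
  stopifnot(length(results) >= 1)
  n <- vapply(results, function(r) r@stats$n_points, numeric(1))
  if (length(unique(n)) != 1)
    stop("results were fitted on different datasets (n_points differ)")
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(topology = r@topology, chi2 = r@stats$chi2,
               reduced_chi2 = r@stats$reduced_chi2, bic = r@stats$bic,
               aic = r@stats$aic, n_params = r@stats$n_params,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$bic), , drop = FALSE]  # order() is a stable sort
  tab$delta_bic <- tab$bic - tab$bic[1]
  rownames(tab) <- NULL
  tab
}

#' Free-energy differences between exchanging states
#'
#' \code{ddG(i -> j) = -R T log(p_j / p_i)} with
#' R = 1.9872e-3 kcal/mol/K; antisymmetric by construction.
#'
#' @param populations named vector of state populations (> 0).
#' @param temperatureK temperature in K.
#' @return matrix of pairwise ddG values in kcal/mol; entry \code{[i, j]} is
#'   the free energy of j relative to i.
#' @examples
#' freeEnergyDifferences(c(N = 0.497, I = 0.006, D = 0.497), 308.15)["N", "I"]
#' @export
freeEnergyDifferences <- function(populations, temperatureK) {
  if (any(populations <= 0)) stop("populations must be > 0")
  R <- 1.9872e-3
  lp <- log(populations)
  out <- -R * temperatureK * outer(lp, lp, function(a, b) b - a)
  dimnames(out) <- list(names(populations), names(populations))
  out
}
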
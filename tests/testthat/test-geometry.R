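rigid_move <- function(x, seed = 1) {
  set.seed(seed)
  th <- runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3)
  sweep(x %*% (Rx %*% Rz), 2, runif(3, -20, 20), "+")
}

toy_atoms <- function(n, resid = seq_len(n)) {
  data.frame(name = "CA", element = "C", resid = resid, resname = "GLY",
             chain = "A")
}

test_that("Kabsch superposition is exact on rigid copies and finds the optimum", {
  set.seed(2)
  x <- matrix(rnorm(45, sd = 5), ncol = 3)
  expect_equal(kabschSuperpose(x, x)$rmsd, 0, tolerance = 1e-12)
  moved <- rigid_move(x, 3)
  fit <- kabschSuperpose(moved, x)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # 4-point toy: grid-search oracle over rotation angles about z, then
  # verify Kabsch attains the brute-force minimum
  a <- matrix(c(0, 0, 0,  3, 0, 0,  3, 4, 0,  0, 4, 1), ncol = 3,
              byrow = TRUE)
  b <- matrix(c(0, 0, 0,  0, 3.2, 0,  -3.9, 3.1, 0,  -4, 0, 0.8), ncol = 3,
              byrow = TRUE)
  kab <- kabschSuperpose(a, b)$rmsd
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  # brute-force search over SO(3): coarse Euler grid then local refinement
  euler_rmsd <- function(p) {
    al <- p[1]; be <- p[2]; ga <- p[3]
    Rz1 <- matrix(c(cos(al), sin(al), 0, -sin(al), cos(al), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(be), 0, -sin(be), 0, 1, 0, sin(be), 0, cos(be)), 3, 3)
    Rz2 <- matrix(c(cos(ga), sin(ga), 0, -sin(ga), cos(ga), 0, 0, 0, 1), 3, 3)
    sqrt(mean(rowSums((ac %*% (Rz1 %*% Ry %*% Rz2) - bc)^2)))
  }
  ang <- seq(0, 2 * pi, length.out = 19)
  half <- seq(0, pi, length.out = 10)
  best <- c(0, 0, 0); best_r <- Inf
  for (al in ang) for (be in half) for (ga in ang) {
    r <- euler_rmsd(c(al, be, ga))
    if (r < best_r) { best_r <- r; best <- c(al, be, ga) }
  }
  grid_best <- stats::optim(best, euler_rmsd,
                            control = list(reltol = 1e-14))$value
  # Kabsch attains (never exceeds) the brute-force rotational minimum
  expect_lte(kab, grid_best + 1e-9)
  expect_equal(kab, grid_best, tolerance = 1e-4)

  # independent cross-check against bio3d's superposition (on a case with
  # no reflection ambiguity; bio3d does not constrain the handedness)
  set.seed(8)
  y <- rigid_move(x, 9) + matrix(rnorm(45, sd = 0.4), ncol = 3)
  bref <- bio3d::rmsd(as.vector(t(y)), as.vector(t(x)), fit = TRUE)
  expect_equal(kabschSuperpose(y, x)$rmsd, bref, tolerance = 1e-3)

  expect_error(kabschSuperpose(x[1:2, ], x[1:2, ]), "3 selected")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line * 2), "collinear")
})

test_that("native-state test honours the 3.0 A boundary inclusively", {
  set.seed(4)
  x <- matrix(rnorm(60, sd = 6), ncol = 3)
  expect_true(nativeStateTest(x, x))
  expect_false(nativeStateTest(x * 2, x))   # scaling grows RMSD
  # construct a displacement with RMSD exactly 3.0
  d <- matrix(rnorm(60), ncol = 3)
  fit <- kabschSuperpose(x + d, x)
  dd <- d * (3.0 / fit$rmsd)
  # rescale iteratively (superposition changes the optimum slightly)
  for (i in 1:30) {
    r <- kabschSuperpose(x + dd, x)$rmsd
    dd <- dd * (3.0 / r)
  }
  expect_true(nativeStateTest(x + dd, x, cutoff = 3.0))
})

test_that("native Q pair list matches a brute-force double loop", {
  set.seed(11)
  n <- 40
  x <- matrix(cumsum(rnorm(3 * n, sd = 1.5)), ncol = 3)
  atoms <- toy_atoms(n)
  pairs <- nativePairsQ(x, atoms, cutoff = 6, minResSep = 3)
  # O(n^2) oracle
  cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(i - j) > 3 && sqrt(sum((x[i, ] - x[j, ])^2)) <= 6) cnt <- cnt + 1
  }
  expect_equal(nrow(pairs), cnt)
  expect_true(all(pairs$i < pairs$j))
  expect_true(all(abs(atoms$resid[pairs$i] - atoms$resid[pairs$j]) > 3))
  expect_true(all(pairs$r0 > 0))
})

test_that("Q evaluates the switching terms as printed", {
  # all pairs at r0 = 5: each term 1/(1+exp(-12.5))
  pairs <- data.frame(i = 1:3, j = 5:7, r0 = 5)
  x <- matrix(0, 8, 3)
  x[5:7, 1] <- 5  # pairs (1,5),(2,6),(3,7) all at distance... build explicitly
  x <- rbind(c(0, 0, 0), c(0, 10, 0), c(0, 20, 0), c(50, 50, 50),
             c(5, 0, 0), c(5, 10, 0), c(5, 20, 0), c(60, 60, 60))
  expect_equal(qFraction(x, pairs), 1 / (1 + exp(-12.5)), tolerance = 1e-12)
  # doubled distances: 1/(1+exp(12.5)) ~ 0
  x2 <- x; x2[5:7, 1] <- 10
  expect_equal(qFraction(x2, pairs), 1 / (1 + exp(12.5)), tolerance = 1e-12)
  # beta -> 0: every term one half
  expect_equal(qFraction(x2, pairs, beta = 0), 0.5)
  # strictly decreasing when one distance grows
  x3 <- x; x3[5, 1] <- 5.4
  expect_lt(qFraction(x3, pairs), qFraction(x, pairs))
})

test_that("rmd pair list applies the index and distance boundaries exactly", {
  set.seed(12)
  n <- 60
  x <- matrix(cumsum(rnorm(3 * n, sd = 1.2)), ncol = 3)
  atoms <- toy_atoms(n)
  pairs <- rmdPairs(x, atoms, cutoff = 12, minIndexSep = 35)
  cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j - i > 35 && sqrt(sum((x[i, ] - x[j, ])^2)) <= 12) cnt <- cnt + 1
  }
  expect_equal(nrow(pairs), cnt)
  expect_true(all(pairs$j - pairs$i >= 36))   # i-j = 35 excluded
  expect_true(all(pairs$r0 <= 12))            # 12.0 inclusive
})

test_that("contact function has the printed values and is decreasing", {
  expect_identical(contactFunction(7.5, 7.5), 0.6)   # exact limit at x = 1
  expect_equal(contactFunction(0), 1)
  x <- 1.6
  printed <- (1 - x^6) / (1 - x^10)
  expect_equal(contactFunction(12, 7.5), printed, tolerance = 1e-12)
  expect_equal(printed, 0.1448, tolerance = 1e-4)
  r <- seq(0.01, 30, by = 0.01)
  expect_true(all(diff(contactFunction(r, 7.5)) < 0))
  # factored form equals the rational form away from the singularity
  rr <- c(2, 5, 7.4999, 7.5001, 11, 20)
  expect_equal(contactFunction(rr, 7.5),
               (1 - (rr / 7.5)^6) / (1 - (rr / 7.5)^10), tolerance = 1e-10)
})

test_that("rmd CV is zero at native, rigid-invariant, and matches brute force", {
  set.seed(13)
  n <- 10
  x <- matrix(runif(30, 0, 15), ncol = 3)
  atoms <- toy_atoms(n)
  pairs <- rmdPairs(x, atoms, cutoff = 12, minIndexSep = 2)
  expect_equal(rmdCv(x, pairs), 0)
  y <- x + matrix(rnorm(30, sd = 1), ncol = 3)
  # brute-force recomputation
  cv <- 0
  for (k in seq_len(nrow(pairs))) {
    r <- sqrt(sum((y[pairs$i[k], ] - y[pairs$j[k], ])^2))
    r0 <- sqrt(sum((x[pairs$i[k], ] - x[pairs$j[k], ])^2))
    C <- function(d) (1 - (d / 7.5)^6) / (1 - (d / 7.5)^10)
    cv <- cv + (C(r) - C(r0))^2
  }
  expect_equal(rmdCv(y, pairs), cv, tolerance = 1e-10)
  expect_equal(rmdCv(rigid_move(y, 5), pairs), rmdCv(y, pairs),
               tolerance = 1e-9)
})

test_that("ratchet bias obeys the pawl branch", {
  expect_equal(rmdBias(1, 2, 5)$energy, 0)             # rho <= rho_m
  expect_equal(rmdBias(1, 2, 5)$force_scale, 0)
  expect_equal(rmdBias(3, 1, 1)$energy, 2)             # kappa/2 * 2^2
  expect_equal(rmdBias(3, 1, 1)$force_scale, -2)
  expect_error(rmdBias(1, 0, -1), "kappa")
})

test_that("contact maps match brute force and behave under differences", {
  # 3-residue toy: residues 1-2 in contact, 3 far away
  atoms <- data.frame(name = c("CA", "CB", "CA", "CA"),
                      element = "C", resid = c(1, 1, 2, 3),
                      resname = "ALA", chain = "A")
  x <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(4, 0, 0), c(30, 0, 0))
  cm <- contactMap(x, atoms, cutoff = 5)
  expect_true(cm["1", "2"]); expect_true(cm["2", "1"])
  expect_false(cm["1", "3"]); expect_false(cm["2", "3"])
  expect_true(all(diag(cm)))
  expect_identical(cm, t(cm))
  expect_true(all(contactDifference(cm, cm) == 0))

  ens <- structureEnsemble(atoms, array(c(x, x), c(4, 3, 2)))
  pm <- ensembleContactProbability(ens)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_equal(pm["1", "2"], 1)
})

test_that("RMSF isolates the oscillating atom and ignores rigid motion", {
  toy <- buildToyNative()
  n <- nrow(toy@native)
  nf <- 24
  fr <- array(0, c(n, 3, nf))
  for (f in seq_len(nf)) {
    x <- toy@native
    # one bead oscillates +-1 A along x in an otherwise rigid body
    x[7, 1] <- x[7, 1] + (if (f %% 2 == 0) 1 else -1)
    fr[, , f] <- rigid_move(x, seed = f)
  }
  ens <- toyEnsemble(toy, fr)
  r <- rmsf(ens)
  # superposition couples the oscillator weakly to the fit, so the
  # recovered amplitude sits slightly below the planted 1.0 A
  expect_equal(unname(r[7]), 1.0, tolerance = 0.1)
  expect_lt(max(r[-7]), 0.15)
  expect_error(rmsf(toyEnsemble(toy, array(toy@native, c(n, 3, 1)))),
               "2 frames")

  # identical frames give zero everywhere
  same <- toyEnsemble(toy, array(rep(toy@native, 3), c(n, 3, 3)))
  expect_true(all(rmsf(same) < 1e-10))
})

test_that("radius of gyration follows the definition", {
  x <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radiusOfGyration(x), 1.0)
  set.seed(14)
  y <- matrix(rnorm(30, sd = 4), ncol = 3)
  m <- runif(10, 1, 16)
  com <- colSums(y * m) / sum(m)
  oracle <- sqrt(sum(m * rowSums(sweep(y, 2, com)^2)) / sum(m))
  expect_equal(radiusOfGyration(y, m), oracle, tolerance = 1e-12)
  expect_equal(radiusOfGyration(y * 3, m), 3 * radiusOfGyration(y, m))
  expect_error(radiusOfGyration(y[1, , drop = FALSE]), "2 atoms")
})

test_that("SASA matches the analytic sphere and shows monotone occlusion", {
  s1 <- sasaShrakeRupley(matrix(0, 1, 3), 1.9)   # explicit radius
  expect_equal(s1$total, 4 * pi * 3.3^2, tolerance = 0.02 * 4 * pi * 3.3^2)
  # fully buried central atom
  shell <- rbind(c(0, 0, 0),
                 as.matrix(expand.grid(x = c(-2, 2), y = c(-2, 2),
                                       z = c(-2, 2))),
                 c(2.8, 0, 0), c(-2.8, 0, 0), c(0, 2.8, 0), c(0, -2.8, 0),
                 c(0, 0, 2.8), c(0, 0, -2.8))
  sb <- sasaShrakeRupley(shell, rep(1.9, nrow(shell)))
  expect_lt(sb$atom[1], 1)
  # bringing two atoms into contact lowers the total area
  far <- sasaShrakeRupley(rbind(c(0, 0, 0), c(20, 0, 0)), c(1.7, 1.7))
  near <- sasaShrakeRupley(rbind(c(0, 0, 0), c(3.5, 0, 0)), c(1.7, 1.7))
  expect_lt(near$total, far$total)
})
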
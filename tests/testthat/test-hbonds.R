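# constructed scenes: a benzene-like ring in the xy-plane plus an amide
# placed by hand

make_scene <- function(h, n, extra_acceptor = NULL) {
  ring <- t(vapply(0:5, function(k) {
    1.39 * c(cos(k * pi / 3), sin(k * pi / 3), 0)
  }, numeric(3)))
  atoms <- data.frame(
    name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "N", "H"),
    element = c(rep("C", 6), "N", "H"),
    resid = c(rep(10, 6), 20, 20),
    resname = c(rep("PHE", 6), "ALA", "ALA"), chain = "A")
  coords <- rbind(ring, n, h)
  if (!is.null(extra_acceptor)) {
    atoms <- rbind(atoms, data.frame(name = "O", element = "O", resid = 30,
                                     resname = "HOH", chain = "A"))
    coords <- rbind(coords, extra_acceptor)
  }
  list(atoms = atoms, coords = coords)
}

test_that("axial amide over a ring is an amide-pi interaction", {
  sc <- make_scene(h = c(0, 0, 3), n = c(0, 0, 4))
  det <- detectAmidePi(sc$coords, sc$atoms)
  expect_equal(nrow(det), 1)
  expect_equal(det$dist, 3, tolerance = 1e-9)
  expect_equal(det$normal_angle, 0, tolerance = 1e-6)
  expect_equal(det$nh_angle, 180, tolerance = 1e-6)
})

test_that("each geometric criterion rejects on its own", {
  # distance: in-plane proton 5 A out
  far <- make_scene(h = c(5, 0, 0), n = c(6, 0, 0))
  expect_equal(nrow(detectAmidePi(far$coords, far$atoms)), 0)
  # normal angle: H at (3,0,1) -> angle ~71.6 degrees > 54.7
  tilted <- make_scene(h = c(3, 0, 1), n = 1.32 * c(3, 0, 1) / sqrt(10) +
                         c(3, 0, 1))
  d <- detectAmidePi(tilted$coords, tilted$atoms)
  expect_equal(nrow(d), 0)
  ang <- acos(abs(sum(c(0, 0, 1) * -c(3, 0, 1)) / sqrt(10))) * 180 / pi
  expect_gt(ang, 54.7)  # analytic geometry behind the rejection
  # N-H...COM angle: N placed sideways so the angle is ~90 degrees
  bent <- make_scene(h = c(0, 0, 3), n = c(1, 0, 3))
  expect_equal(nrow(detectAmidePi(bent$coords, bent$atoms)), 0)
  # criterion 4: a competing non-aromatic acceptor right under the proton
  blocked <- make_scene(h = c(0, 0, 3), n = c(0, 0, 4),
                        extra_acceptor = c(0, 0.4, 1.2))
  expect_equal(nrow(detectAmidePi(blocked$coords, blocked$atoms)), 0)
})

test_that("hydrogen-bond detector applies both thresholds", {
  atoms <- data.frame(name = c("N", "H", "O"), element = c("N", "H", "O"),
                      resid = c(1, 1, 5), resname = c("ALA", "ALA", "SER"),
                      chain = "A")
  # collinear N-H...O at 1.9 A: detected
  x <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  hb <- detectHydrogenBonds(x, atoms,
                            donors = data.frame(n = 1, h = 2))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$dist, 1.9)
  expect_equal(hb$angle, 180)
  # 2.6 A: rejected (boundary is < 2.5)
  x2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.6, 0, 0))
  expect_equal(nrow(detectHydrogenBonds(x2, atoms,
                                        donors = data.frame(n = 1, h = 2))),
               0)
  # angle 100 degrees: rejected
  d <- 1.9
  a100 <- c(1, 0, 0) + d * c(cos(100 * pi / 180), sin(100 * pi / 180), 0)
  x3 <- rbind(c(0, 0, 0), c(1, 0, 0), a100)
  expect_equal(nrow(detectHydrogenBonds(x3, atoms,
                                        donors = data.frame(n = 1, h = 2))),
               0)
  # missing amide proton errors with the residue name
  atoms4 <- data.frame(name = c("N", "CA", "N", "CA"),
                       element = c("N", "C", "N", "C"),
                       resid = c(1, 1, 2, 2), resname = "ALA", chain = "A")
  x4 <- matrix(rnorm(12), ncol = 3)
  expect_error(detectHydrogenBonds(x4, atoms4), "ALA2")
})

test_that("detectors agree with an exhaustive brute-force checker", {
  # random scenes: ring at the origin, amide and a stray acceptor placed
  # randomly; brute-force evaluation written independently below
  brute <- function(coords, atoms) {
    ring <- coords[1:6, ]
    com <- colMeans(ring)
    cen <- sweep(ring, 2, com)
    nrm <- svd(cen)$v[, 3]
    h <- coords[8, ]; n <- coords[7, ]; o <- coords[9, ]
    # conventional H bond to the acceptor?
    hb <- FALSE
    if (sqrt(sum((o - h)^2)) < 2.5) {
      v1 <- n - h; v2 <- o - h
      a <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (a > 120) hb <- TRUE
    }
    v <- com - h
    dd <- sqrt(sum(v^2))
    na <- acos(sum(nrm * v) / (sqrt(sum(nrm^2)) * dd)) * 180 / pi
    na <- min(na, 180 - na)
    v1 <- n - h
    nh <- acos(sum(v1 * v) / sqrt(sum(v1^2)) / dd) * 180 / pi
    list(pi_bond = (dd < 4.5) && (na < 54.7) && (nh > 120) && !hb,
         h_bond = hb)
  }
  set.seed(99)
  n_scenes <- 400
  mismatch <- 0
  for (s in seq_len(n_scenes)) {
    sc <- make_scene(h = runif(3, -4, 4), n = runif(3, -5, 5),
                     extra_acceptor = runif(3, -4, 4))
    got <- detectAmidePi(sc$coords, sc$atoms)
    hb <- detectHydrogenBonds(sc$coords, sc$atoms,
                              donors = data.frame(n = 7, h = 8),
                              acceptors = 9)
    want <- brute(sc$coords, sc$atoms)
    if ((nrow(got) > 0) != want$pi_bond) mismatch <- mismatch + 1
    if ((nrow(hb) > 0) != want$h_bond) mismatch <- mismatch + 1
  }
  expect_equal(mismatch, 0)
})

test_that("geometric detectors are invariant under rigid motion", {
  sc <- make_scene(h = c(0.4, 0.2, 2.8), n = c(0.5, 0.3, 3.9),
                   extra_acceptor = c(8, 8, 8))
  base <- detectAmidePi(sc$coords, sc$atoms)
  expect_equal(nrow(base), 1)
  for (seed in 1:5) {
    set.seed(seed)
    th <- runif(3, -pi, pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                   0, -sin(th[1]), cos(th[1])), 3, 3)
    Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                   0, 0, 1), 3, 3)
    moved <- sweep(sc$coords %*% (Rx %*% Rz), 2, runif(3, -30, 30), "+")
    det <- detectAmidePi(moved, sc$atoms)
    expect_equal(nrow(det), 1)
    expect_equal(det$dist, base$dist, tolerance = 1e-9)
    expect_equal(det$normal_angle, base$normal_angle, tolerance = 1e-6)
  }
})

test_that("ensemble amide-pi frequencies count frames correctly", {
  yes <- make_scene(h = c(0, 0, 3), n = c(0, 0, 4))
  no <- make_scene(h = c(9, 0, 3), n = c(9, 0, 4))
  fr <- array(0, c(8, 3, 4))
  fr[, , 1] <- yes$coords; fr[, , 2] <- no$coords
  fr[, , 3] <- yes$coords; fr[, , 4] <- no$coords
  ens <- structureEnsemble(yes$atoms, fr)
  p <- ensembleAmidePiProbability(ens)
  expect_equal(p$perAmide$frequency[p$perAmide$resid == 20], 0.5)
  expect_equal(p$perRingType$frequency[p$perRingType$resname == "PHE"], 0.5)
  allyes <- structureEnsemble(yes$atoms,
                              array(rep(yes$coords, 3), c(8, 3, 3)))
  pa <- ensembleAmidePiProbability(allyes)
  expect_equal(pa$perAmide$frequency[pa$perAmide$resid == 20], 1.0)
})

test_that("Trp contributes two rings and His inclusion is switchable", {
  # minimal Trp sidechain ring system
  atoms <- data.frame(
    name = c("CG", "CD1", "NE1", "CE2", "CD2", "CZ2", "CH2", "CZ3", "CE3"),
    element = c("C", "C", "N", "C", "C", "C", "C", "C", "C"),
    resid = 1, resname = "TRP", chain = "A")
  # idealised indole geometry (planar, approximate)
  x <- rbind(c(0, 0, 0), c(1.2, 0.8, 0), c(2.4, 0, 0), c(1.9, -1.3, 0),
             c(0.5, -1.3, 0), c(2.6, -2.5, 0), c(1.9, -3.7, 0),
             c(0.5, -3.7, 0), c(-0.2, -2.5, 0))
  ens <- structureEnsemble(atoms, x)
  rings <- buildRings(ens)
  expect_equal(length(rings), 2)
  expect_setequal(vapply(rings, `[[`, "", "label"), c("5-ring", "6-ring"))
  expect_true(all(vapply(rings, function(r)
    abs(sqrt(sum(r$normal^2)) - 1) < 1e-10, logical(1))))
  his <- data.frame(name = c("CG", "ND1", "CD2", "CE1", "NE2"),
                    element = c("C", "N", "C", "C", "N"),
                    resid = 2, resname = "HIS", chain = "A")
  hx <- rbind(c(0, 0, 0), c(1.3, 0.5, 0), c(0.6, -1.3, 0), c(2.2, -0.6, 0),
              c(1.9, -1.6, 0))
  hens <- structureEnsemble(his, hx)
  expect_equal(length(buildRings(hens)), 1)
  expect_equal(length(buildRings(hens, includeHis = FALSE)), 0)
})
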
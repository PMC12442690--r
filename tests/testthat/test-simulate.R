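test_that("CEST engine matches an independent ODE integration", {
  # single state, several offsets
  m <- single_state_model(shift = 120, R1 = 1.5, R2 = 10)
  sc <- cestScheme(700, "15N", 60, 0.4, c(118, 119.5, 120, 120.5, 122))
  prof <- simulateCest(m, sc)
  lar <- larmorMHz("15N", 700)
  for (k in seq_along(sc@offsets_ppm)) {
    om <- 2 * pi * lar * (120 - sc@offsets_ppm[k])
    oracle <- ode_cest_ratio(1, 1.5, 10, om, 2 * pi * 60, 0.4,
                             matrix(0, 1, 1))
    expect_equal(prof@data$y[k], unname(oracle), tolerance = 1e-6)
  }
  # frozen on-resonance value computed with the ODE oracle: the
  # magnetization nutates through 24 full periods during Tex = 0.4 s and
  # decays at ~(R1+R2)/2, leaving ~0.10 of the signal
  expect_equal(prof@data$y[prof@data$x == 120], 0.1003, tolerance = 1e-3)

  # three-state fixture model, spot-check a handful of offsets
  fx <- lysozymeFixture("A42")
  m3 <- fixtureModel(fx, "15N")
  sc3 <- cestScheme(700, "15N", 15, 0.4, c(123.4, 126.8, 128.5, 131.4))
  prof3 <- simulateCest(m3, sc3, observe = "N")
  K <- buildRateMatrix(m3)
  st <- m3@states
  for (k in seq_along(sc3@offsets_ppm)) {
    om <- 2 * pi * lar * (st$shift_ppm - sc3@offsets_ppm[k])
    oracle <- ode_cest_ratio(st$population, st$R1, st$R2, om, 2 * pi * 15,
                             0.4, K)
    expect_equal(prof3@data$y[k], unname(oracle[1]), tolerance = 1e-6)
  }
})

test_that("B1 -> 0 leaves equilibrium magnetization untouched", {
  m <- single_state_model(R1 = 1.5, R2 = 10)
  sc <- cestScheme(700, "15N", 1e-6, 0.4, seq(115, 125, 1))
  prof <- simulateCest(m, sc)
  # magnetization starts at equilibrium and the R1*Meq inflow returns it
  # there: a vanishing saturation field gives a flat profile at 1
  expect_true(all(abs(prof@data$y - 1) < 1e-6))
})

test_that("three-state fixture shows three dips, the intermediate shallowest", {
  fx <- lysozymeFixture("A42")
  m <- fixtureModel(fx, "15N")
  sc <- defaultCestScheme(16.4, 60)
  prof <- simulateCest(m, sc, observe = "N")
  x <- prof@data$x; y <- prof@data$y
  mins <- x[which(diff(sign(diff(y))) == 2) + 1]
  near <- function(v) any(abs(mins - v) <= 0.4)
  expect_true(near(123.4))  # N
  expect_true(near(126.8))  # D
  expect_true(near(131.4))  # I
  depth <- function(v) max(y) - y[which.min(abs(x - v))]
  expect_lt(depth(131.4), depth(126.8))
  expect_lt(depth(131.4), depth(123.4))
  expect_true(all(y >= -1 & y <= 1))
})

test_that("two-state CEST profile is invariant under state relabelling", {
  mA <- two_state_model(pB = 0.3, kex = 40, dwN = 119, dwD = 124,
                        R2N = 12, R2D = 6)
  # same physical system with the states listed in the other order
  mB <- exchangeModel(
    states = data.frame(label = c("D", "N"), population = c(0.3, 0.7),
                        shift_ppm = c(124, 119), R1 = 1.5, R2 = c(6, 12)),
    rates = data.frame(from = "D", to = "N", kex = 40))
  sc <- cestScheme(700, "15N", 25, 0.3, seq(115, 128, 0.25))
  pA <- simulateCest(mA, sc, observe = "N")
  pB_ <- simulateCest(mB, sc, observe = "N")
  expect_equal(pA@data$y, pB_@data$y, tolerance = 1e-12)
})

test_that("slow-exchange CEST dips sit at the state shifts", {
  m <- two_state_model(pB = 0.3, kex = 8, dwN = 118, dwD = 125)
  sc <- cestScheme(700, "15N", 12, 0.5, seq(114, 129, 0.02))
  prof <- simulateCest(m, sc, observe = "N")
  x <- prof@data$x; y <- prof@data$y
  mins <- x[which(diff(sign(diff(y))) == 2) + 1]
  expect_lt(min(abs(mins - 118)), 0.05)
  expect_lt(min(abs(mins - 125)), 0.05)
})

test_that("CPMG without exchange returns R2 exactly; dispersion decreases", {
  m <- single_state_model(R2 = 13)
  sc <- defaultCpmgScheme()
  prof <- simulateCpmg(m, sc)
  expect_equal(prof@data$y, rep(13, 20), tolerance = 1e-10)

  fx <- lysozymeFixture("A42")
  m3 <- fixtureModel(fx, "15N")
  p3 <- simulateCpmg(m3, sc, observe = "N")
  expect_gt(p3@data$y[1], p3@data$y[20])           # quenched at high nu
  expect_true(all(is.finite(p3@data$y) & p3@data$y > 0))
})

test_that("two-state CPMG agrees with the Carver-Richards closed form", {
  dw <- ppmToRadSec(3, "15N", 800)   # 3 ppm at 81.1 MHz 15N
  m <- exchangeModel(
    states = data.frame(label = c("A", "B"), population = c(0.98, 0.02),
                        shift_ppm = c(120, 123), R1 = 1.5, R2 = c(10, 10)),
    rates = data.frame(from = "A", to = "B", kex = 500))
  sc <- defaultCpmgScheme(800)
  prof <- simulateCpmg(m, sc, observe = "A")
  oracle <- carver_richards_r2eff(sc@nu_cpmg_Hz, 0.98, 500, dw, 10, 10)
  expect_equal(prof@data$y, oracle, tolerance = 0.02)
})

test_that("fast-pulsing CPMG limit approaches the mixed-average R2", {
  # exchange fast on the Tcp scale so magnetization fully mixes
  m <- exchangeModel(
    states = data.frame(label = c("A", "B"), population = c(0.6, 0.4),
                        shift_ppm = c(120, 121), R1 = 1.5, R2 = c(12, 4)),
    rates = data.frame(from = "A", to = "B", kex = 4000))
  sc <- cpmgScheme(800, "15N", 0.040, c(25, 2000))
  prof <- simulateCpmg(m, sc, observe = "A")
  wavg <- 0.6 * 12 + 0.4 * 4
  expect_equal(prof@data$y[2], wavg, tolerance = 0.02 * wavg)
})

test_that("R2eff from intensities matches the definition and round-trips", {
  expect_equal(r2effFromIntensity(1, 1, 0.04), 0)
  expect_equal(r2effFromIntensity(exp(-1), 1, 0.04), 25)
  expect_error(r2effFromIntensity(-1, 1, 0.04), "positive")
  # round trip through simulated CPMG intensities
  m <- two_state_model(pB = 0.05, kex = 300, dwN = 120, dwD = 122.5)
  sc <- defaultCpmgScheme()
  prof <- simulateCpmg(m, sc, observe = "N")
  I0 <- 0.95
  I <- I0 * exp(-prof@data$y * 0.040)
  expect_equal(r2effFromIntensity(I, I0, 0.040), prof@data$y,
               tolerance = 1e-9)
})

test_that("Trott-Palmer closed form behaves as printed", {
  # direct evaluation example
  expect_equal(r1rhoTrottPalmer(1, 10, 0.01, 2 * pi * 300, 100,
                                2 * pi * 1000, 0),
               10.0825, tolerance = 1e-3)
  # pB = 0 removes the exchange term
  th <- atan2(500, 200)
  expect_equal(r1rhoTrottPalmer(1, 10, 0, 2 * pi * 300, 100, 500, 200),
               cos(th)^2 * 1 + sin(th)^2 * 10, tolerance = 1e-12)
  # omega1 -> infinity quenches Rex
  big <- r1rhoTrottPalmer(1, 10, 0.02, 2 * pi * 300, 200, 2 * pi * 1e6, 0)
  expect_equal(big, 10, tolerance = 1e-4)
  # Rex non-increasing in omega1
  w1 <- 2 * pi * seq(50, 3000, length.out = 40)
  rex <- r1rhoTrottPalmer(0, 0, 0.02, 2 * pi * 300, 200, w1, 0) / sin(pi / 2)^2
  expect_true(all(diff(rex) <= 1e-12))
  # undefined tilt errors
  expect_error(r1rhoTrottPalmer(1, 10, 0, 0, 100, 0, 0), "tilt")
})

test_that("Trott-Palmer agrees with numerical spin-lock decay (pB small)", {
  # two-state free decay under a spin lock, starting along the effective
  # field of the dominant state; decay rate extracted by log-linear fit
  pB <- 0.015; kex <- 300; R1 <- 1.2; R2 <- 9
  dw <- ppmToRadSec(2, "15N", 700)
  for (setup in list(c(w1 = 2 * pi * 500, dA = 0),
                     c(w1 = 2 * pi * 800, dA = 2 * pi * 300))) {
    w1 <- setup[["w1"]]; dA <- setup[["dA"]]
    K <- matrix(c(-pB * kex, pB * kex, (1 - pB) * kex, -(1 - pB) * kex), 2, 2)
    # Bloch-McConnell with Meq = 0 (free decay, as the closed form assumes)
    deriv <- function(t, y, parms) {
      dy <- numeric(6)
      Om <- c(dA, dA + dw)
      for (s in 1:2) {
        ix <- 3 * (s - 1) + 1
        dy[ix]     <- -R2 * y[ix] + Om[s] * y[ix + 1]
        dy[ix + 1] <- -Om[s] * y[ix] - R2 * y[ix + 1] + w1 * y[ix + 2]
        dy[ix + 2] <- -w1 * y[ix + 1] - R1 * y[ix + 2]
        for (t2 in 1:2) {
          jx <- 3 * (t2 - 1) + 1
          dy[ix:(ix + 2)] <- dy[ix:(ix + 2)] + K[s, t2] * y[jx:(jx + 2)]
        }
      }
      list(dy)
    }
    theta <- atan2(w1, dA + pB * dw)
    eff <- c(sin(theta), 0, cos(theta))   # effective-field axis (x, z plane)
    y0 <- c((1 - pB) * eff[1], 0, (1 - pB) * eff[3],
            pB * eff[1], 0, pB * eff[3])
    times <- seq(0, 0.08, by = 0.008)
    out <- deSolve::ode(y0, times, deriv, NULL, rtol = 1e-10, atol = 1e-12)
    proj <- out[, 2] * eff[1] + out[, 4] * eff[3]
    rate <- -stats::coef(stats::lm(log(proj) ~ times))[2]
    closed <- r1rhoTrottPalmer(R1, R2, pB, dw, kex, w1, dA)
    expect_equal(unname(rate), closed, tolerance = 0.05 * closed)
  }
})

test_that("schemes validate their grids", {
  expect_error(cestScheme(700, "15N", -5, 0.3, 1:10), "B1")
  expect_error(cestScheme(700, "15N", 15, 0.3, c(1, 3, 2)), "monotone")
  expect_error(cpmgScheme(800, "15N", 0.040, c(5, 100)), "echo count")
  expect_error(simulateCest(single_state_model(),
                            cestScheme(700, "15N", 15, 0.3, 1:5),
                            observe = "Z"), "unknown observed state")
})
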
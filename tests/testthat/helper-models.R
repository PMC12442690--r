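# shared builders for the exchange tests

two_state_model <- function(pB = 0.5, kex = 100, dwN = 120, dwD = 123,
                            R1 = 1.5, R2N = 10, R2D = 8) {
  exchangeModel(
    states = data.frame(label = c("N", "D"), population = c(1 - pB, pB),
                        shift_ppm = c(dwN, dwD), R1 = R1, R2 = c(R2N, R2D)),
    rates = data.frame(from = "N", to = "D", kex = kex),
    topology = "two_state")
}

single_state_model <- function(shift = 120, R1 = 1.5, R2 = 10) {
  exchangeModel(states = data.frame(label = "A", population = 1,
                                    shift_ppm = shift, R1 = R1, R2 = R2))
}

# small CEST/CPMG datasets for fast fitting tests: one residue, one B1,
# reduced offset grid
small_cest_scheme <- function(B1 = 25, from = 115, to = 130, by = 0.5,
                              Tex = 0.4, B0 = 700)
  cestScheme(B0, "15N", B1, Tex, seq(from, to, by = by))

# independent Bloch-McConnell integration with deSolve (the ODE oracle):
# states with populations p, rates R1/R2, offsets Omega (rad/s relative to
# the saturation carrier), nutation w1 (rad/s), exchange matrix K
ode_cest_ratio <- function(p, R1, R2, Omega, w1, Tex, K) {
  S <- length(p)
  deriv <- function(t, y, parms) {
    dy <- numeric(3 * S)
    for (s in seq_len(S)) {
      ix <- 3 * (s - 1) + 1; iy <- ix + 1; iz <- ix + 2
      dy[ix] <- -R2[s] * y[ix] + Omega[s] * y[iy]
      dy[iy] <- -Omega[s] * y[ix] - R2[s] * y[iy] + w1 * y[iz]
      dy[iz] <- -w1 * y[iy] - R1[s] * (y[iz] - p[s])
      for (t2 in seq_len(S)) {
        jx <- 3 * (t2 - 1) + 1
        dy[ix] <- dy[ix] + K[s, t2] * y[jx]
        dy[iy] <- dy[iy] + K[s, t2] * y[jx + 1]
        dy[iz] <- dy[iz] + K[s, t2] * y[jx + 2]
      }
    }
    list(dy)
  }
  y0 <- numeric(3 * S)
  y0[3 * seq_len(S)] <- p
  # hmax keeps the integrator honest through the fast nutation oscillation
  out <- deSolve::ode(y0, c(0, Tex), deriv, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12, hmax = 2e-4,
                      maxsteps = 1e6)
  mz <- out[nrow(out), 1 + 3 * seq_len(S)]
  mz / p
}

# Carver-Richards closed form for two-state CPMG (test oracle)
carver_richards_r2eff <- function(nu, pA, kex, dw, R2A, R2B) {
  pB <- 1 - pA
  dR <- R2A - R2B
  psi <- (dR - pA * kex + pB * kex)^2 - dw^2 + 4 * pA * pB * kex^2
  zeta <- 2 * dw * (dR - pA * kex + pB * kex)
  rt <- sqrt(psi^2 + zeta^2)
  Dp <- 0.5 * (1 + (psi + 2 * dw^2) / rt)
  Dm <- 0.5 * (-1 + (psi + 2 * dw^2) / rt)
  etap <- sqrt(2) / (4 * nu) * sqrt(psi + rt)
  etam <- sqrt(2) / (4 * nu) * sqrt(-psi + rt)
  0.5 * (R2A + R2B + kex -
         2 * nu * acosh(Dp * cosh(etap) - Dm * cos(etam)))
}

# single-residue triangular dataset at reduced size (fast fitting tests)
small_triangular_dataset <- function(sigma_cest = 0.005, sigma_cpmg = 0.3,
                                     seed = 1) {
  fx <- lysozymeFixture("A42")
  cest <- generateCestDataset(
    fx, schemes = list(small_cest_scheme(15, 118, 133, 0.4),
                       small_cest_scheme(60, 118, 133, 0.4)),
    noise = noiseModel(sigma_cest, seed = seed))
  cpmg <- generateCpmgDataset(fx, noise = noiseModel(sigma_cpmg,
                                                     seed = seed + 1))
  profileDataset(c(profiles(cest), profiles(cpmg)))
}
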
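# Fitting tests run on deliberately small single-residue datasets so the
# whole suite stays fast; the full three-residue study conditions are
# exercised in test-acceptance.R.

test_that("noiseless single-residue data are recovered almost exactly", {
  ds <- small_triangular_dataset(sigma_cest = 0, sigma_cpmg = 0, seed = 3)
  fit <- globalFit(ds, "triangular", nstarts = 1, seed = 1)
  g <- function(n) fittedParameter(fit, n)
  expect_equal(g("kex_NI"), 27.7, tolerance = 1e-3)
  expect_equal(g("kex_ID"), 94.3, tolerance = 1e-3)
  expect_equal(g("kex_ND"), 5.0, tolerance = 1e-3)
  expect_equal(g("p_I"), 0.006, tolerance = 1e-3)
  expect_equal(g("dw_A42_15N_I"), 131.4, tolerance = 1e-4)
  expect_equal(g("dw_A42_15N_N"), 123.4, tolerance = 1e-5)
  # rms misfit in intensity-ratio units (sigma floor is 1e-6 for sigma = 0)
  expect_lt(sqrt(fitStats(fit)$chi2 / fitStats(fit)$n_points) * 1e-6, 1e-5)
})

test_that("noisy single-residue fit lands near the generating kinetics", {
  ds <- small_triangular_dataset(seed = 17)
  fit <- globalFit(ds, "triangular", nstarts = 2, seed = 2)
  # the reduced single-residue grid carries less information than the full
  # study dataset, so the statistical error on the rates is larger here
  expect_equal(fittedParameter(fit, "kex_NI"), 27.7, tolerance = 0.25)
  expect_equal(fittedParameter(fit, "p_I"), 0.006, tolerance = 0.25)
  # chi-square consistent with the generating noise
  expect_gt(fitStats(fit)$reduced_chi2, 0.7)
  expect_lt(fitStats(fit)$reduced_chi2, 1.4)
  # parameter uncertainties are finite and positive
  expect_true(all(is.finite(parameters(fit)$sd)))
})

test_that("single-state data fitted as two-state give a vanishing minor state", {
  m <- single_state_model(shift = 121, R1 = 1.3, R2 = 10)
  sc <- small_cest_scheme(25)
  set.seed(9)
  profs <- lapply(c(15, 60), function(b1) {
    p <- simulateCest(m, small_cest_scheme(b1))
    p@residue <- "X1"; p@temperatureK <- 308.15
    p@data$y <- p@data$y + rnorm(nrow(p@data), 0, 0.003)
    p@data$sigma <- 0.003
    p@meta$observe <- "N"
    p
  })
  fit <- globalFit(profileDataset(profs), "two_state", nstarts = 2,
                   seed = 4)
  expect_lt(fittedParameter(fit, "p_D"), 0.001)
})

test_that("fit objective is monotone over optimizer iterations", {
  ds <- small_triangular_dataset(seed = 5)
  fit <- globalFit(ds, "triangular", nstarts = 1, seed = 1,
                   computeSd = FALSE)
  tr <- fit@convergence$rsstrace
  expect_true(all(diff(tr) <= 1e-6 * tr[-length(tr)]))
})

test_that("under-determined fits and empty datasets are rejected", {
  expect_error(globalFit(profileDataset(list()), "triangular"), "empty")
  m <- single_state_model()
  p <- simulateCest(m, cestScheme(700, "15N", 15, 0.3, seq(119, 121, 0.5)))
  p@residue <- "X1"; p@temperatureK <- 308.15
  p@data$sigma <- 0.005
  p@meta$observe <- "N"
  expect_error(globalFit(profileDataset(list(p)), "triangular"),
               "under-determined")
})

test_that("model selection sorts by BIC with the stated penalties", {
  mk <- function(topology, chi2, k, n) {
    new("FitResult", topology = topology,
        parameters = data.frame(name = character(), value = numeric(),
                                sd = numeric()),
        stats = list(chi2 = chi2, reduced_chi2 = chi2 / (n - k),
                     bic = chi2 + k * log(n), aic = chi2 + 2 * k,
                     n_points = n, n_params = k),
        convergence = list(converged = TRUE))
  }
  r1 <- mk("triangular", 100, 10, 500)
  r2 <- mk("N-I-D", 150, 8, 500)
  tab <- modelSelection(list(r2, r1))
  expect_equal(tab$topology[1], "triangular")
  expect_equal(tab$bic, tab$chi2 + tab$n_params * log(500))
  expect_equal(tab$aic, tab$chi2 + 2 * tab$n_params)
  # stable sort: identical results keep input order
  tab2 <- modelSelection(list(r2, mk("N-D-I", 150, 8, 500)))
  expect_equal(tab2$topology, c("N-I-D", "N-D-I"))
  # nested models on null data: the bigger model pays the BIC penalty
  null_small <- mk("two_state", 500, 5, 500)
  null_big <- mk("triangular", 498, 12, 500)
  expect_equal(modelSelection(list(null_big, null_small))$topology[1],
               "two_state")
  # mixed datasets refuse to rank
  expect_error(modelSelection(list(r1, mk("N-D-I", 90, 8, 400))),
               "different datasets")
})
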
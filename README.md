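# foldex

Chemical-exchange NMR fitting and structural-ensemble analysis for sparsely
populated protein folding intermediates.

Amyloidogenic variants of human lysozyme (here the I59T variant at pH 1.2)
populate a transient intermediate state — native-like α-domain, disordered
β-domain and C-helix — at only ≈0.6% of the molecules near the tertiary
melting temperature. States that sparse are invisible to direct NMR
spectra but leave fingerprints in saturation-transfer (CEST) and
relaxation-dispersion (CPMG, R1ρ) experiments. `foldex` implements the
quantitative machinery such a study needs:

* **Forward models.** Bloch–McConnell evolution for arbitrary N-site
  exchange: CEST intensity ratios via matrix-exponential propagation of
  the full (Mx, My, Mz per state + equilibrium-return) magnetization
  vector, constant-time CPMG echo trains with ideal refocusing pulses,
  and the Trott–Palmer closed form
  `R1ρ = R1 cos²θ + (R2 + Rex) sin²θ`,
  `Rex = pB Δω² kex / ((δA+Δω)² + ω1² + kex²)`.
* **Global fitting.** Simultaneous Levenberg–Marquardt fits of many
  CEST/CPMG profiles with shared kinetics (populations `p_N, p_I, p_D` on
  a simplex, pairwise exchange rates `kex`) and per-residue shifts and
  relaxation rates; exchange-topology comparison (two-state, the three
  sequential three-state schemes N–I–D / N–D–I / I–N–D, and the
  triangular model) ranked by χ², BIC and AIC; two-state thermal-series
  and CD melting-curve fits.
* **Synthetic data.** A seeded generator reproducing the study's
  acquisition grids and the published kinetic/spectroscopic parameters,
  so every stage of the pipeline is testable without the (undeposited)
  raw spectra.
* **Ensemble geometry.** Fraction of native contacts
  `Q = ⟨1/(1+exp(β(r−λr0)))⟩` (β = 5 Å⁻¹, λ = 1.5), the ratchet-and-pawl
  collective variable `CV = Σ (C_ij − C_ij^nat)²` with
  `C = (1−x⁶)/(1−x¹⁰)`, heavy-atom contact maps (5 Å), hydrogen-bond and
  amide-π detection, GROMOS clustering, RMSF, radius of gyration,
  Shrake–Rupley SASA, and free-energy landscapes over (Cα-RMSD, Q) with
  Gaussian smoothing and 11 kJ/mol basin extraction.
* **Ratchet-and-pawl demonstration.** A 30-bead Gō-type model under
  overdamped Langevin dynamics showing that the history-dependent bias
  `κ/2 (ρ−ρ_m)²` (active only when the system backtracks along the CV)
  drives folding that essentially never happens unbiased at the same
  budget.

## Worked example

Generate the canonical three-residue dataset (A42, I56, T59 at 35 °C:
¹⁵N CEST at B1 = 15/60 Hz on the 16.4 T grid, amide ¹H CEST, CPMG at
Tcp = 40 ms — native and denatured peaks observed throughout) and run the
global triangular fit:

```r
library(foldex)

mk <- function(res, sb) {
  fx <- lysozymeFixture(res)
  c(profiles(generateCestDataset(fx, noise = noiseModel(0.005, seed = sb))),
    profiles(generateCpmgDataset(fx, noise = noiseModel(0.3, seed = sb + 1))),
    profiles(generateCestDataset(fx, schemes = list(defaultAmideCestScheme()),
                                 noise = noiseModel(0.005, seed = sb + 2))))
}
dataset <- profileDataset(c(mk("A42", 11), mk("I56", 21), mk("T59", 31)))
fit <- globalFit(dataset, "triangular", nstarts = 2, seed = 1)
fit
#> FitResult [triangular]: chi2 = 1695.44, red. chi2 = 1.095, BIC = 2042.1, AIC = 1789.4 (n = 1596, k = 47)

pt <- parameters(fit)
pt[pt$name %in% c("p_I", "kex_NI", "kex_ID", "dw_A42_15N_I"), ]
#>           name     value        sd
#> 2          p_I   0.00594 0.0001467
#> 4       kex_NI  28.09182 1.1835702
#> 5       kex_ID  96.22687 3.1708135
#> 8 dw_A42_15N_I 131.41428 0.0134964
```

The fitted intermediate population (0.59%), the N–I and I–D exchange rates
(28.1 and 96.2 s⁻¹) and the A42 intermediate ¹⁵N shift (131.41 ppm) recover
the generating values — 0.006, 27.7 s⁻¹, 94.3 s⁻¹ and 131.4 ppm — within a
couple of standard deviations, and the reduced χ² near 1 says the fit
explains the data at the generating noise level. Topology comparison on the
same dataset (`modelSelection` over the candidate exchange schemes) ranks
the triangular model first by BIC.

Free energies follow from the populations:

```r
freeEnergyDifferences(c(N = 0.497, I = 0.006, D = 0.497), 308.15)["N", "I"]
#> [1] 2.704671   # kcal/mol
```

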
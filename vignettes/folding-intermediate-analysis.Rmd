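---
title: "Quantifying a sparse folding intermediate: exchange models, global fits, and ensemble geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a sparse folding intermediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Amyloidogenic variants of human lysozyme populate a partially unfolded
intermediate (I) in equilibrium with the native state (N) and the denatured
ensemble (D). At low pH and near the tertiary melting temperature (35 °C)
this intermediate reaches only about 0.6% population, far below what direct
spectroscopy can resolve, but CEST and CPMG relaxation-dispersion NMR can
see it through its exchange with the visible states. `foldex` implements
the computational side of such a study end to end: forward simulation of
CEST/CPMG/R1rho observables for arbitrary N-site exchange, global fitting
with exchange-topology model selection, a seeded synthetic-data generator
that stands in for the (undeposited) raw spectra, structure-ensemble
geometry used to rationalize the intermediate's anomalous amide-proton
shifts, and a desk-scale demonstration of ratchet-and-pawl (rMD) biasing.

# Chemical exchange machinery

## The exchange model

An `ExchangeModel` holds per-state populations, chemical shifts, R1/R2, and
pairwise exchange rates `kex` (the sum of forward and reverse rate
constants on an edge). Directional rates follow the detailed-balance
convention

```
k(i -> j) = kex_ij * p_j / (p_i + p_j)
```

so stationarity (`K p = 0`) and detailed balance hold by construction for
any population vector — the fit can therefore never wander into a
thermodynamically inconsistent rate matrix.

## CEST

For every saturation offset the full magnetization vector — (Mx, My, Mz)
per state plus one constant element that carries the `R1 * Meq` return flux
— is propagated with a matrix exponential, which is exact for a
piecewise-constant Liouvillian. The reported observable is
`Mz(observed state, Tex) / Mz(observed state, 0)`, i.e. the ratio against
the reference spectrum acquired with `Tex = 0`. The observed state defaults
to the largest-population state (ties broken by state order) and can be set
explicitly, since both the native and the denatured peaks of each residue
are resolved and measured in this regime.

Because magnetization starts at thermal equilibrium and the engine models
the return to equilibrium, a vanishing saturation field leaves the profile
flat at 1 — the far-offset baseline carries essentially no R1 information.
This is why the fit initializes R1 at typical amide values (1.2 s^-1 for
15N, 2.0 s^-1 for 1H) rather than from the baseline. R1 remains a fitted,
weakly determined nuisance parameter.

Anti-phase coherence pathways of the amide-proton experiments are not
modelled; 1H CEST is generated and fitted with the same longitudinal-
saturation engine. TROSY effects and temperature-dependent shift drifts are
likewise out of scope.

## CPMG

Constant-time CPMG is propagated as in-phase single-quantum coherence
(complex M+ per state) through `[tau - 180 - tau]^(2n)` with ideal,
instantaneous 180-degree pulses implemented as complex conjugation, with
`n = round(nu_cpmg * Tcp)` and `tau = Tcp / (4 n)`. Grids are restricted to
`n >= 1`. `R2eff = -(1/Tcp) log(|M_obs(Tcp)| / p_obs)`. A common frequency
offset contributes only a global phase, so shifts enter relative to the
first state.

## R1rho

The rotating-frame rate uses the closed form for asymmetric populations:
`R1rho = R1 cos^2(theta) + (R2 + Rex) sin^2(theta)` with
`Rex = pB dw^2 kex / ((dA + dw)^2 + w1^2 + kex^2)`. The tilt angle, which
the closed form leaves open, is taken as `theta = atan2(w1, dA + pB * dw)`
— the offset measured from the population-averaged resonance, the standard
convention in this limit. Whether `dA` in the denominator is measured from
the A-state or the averaged resonance is genuinely ambiguous in this
parameterization; the package implements the printed form verbatim and
treats the fitted shift difference as a nuisance parameter, reporting only
the identifiable composite `phi = pB * dw^2` together with `kex` and `R2`.

# Global fitting

`globalFit()` minimizes the sigma-weighted residual sum over every profile
simultaneously with Levenberg-Marquardt. Kinetic parameters (populations,
pairwise rates) are shared across residues per temperature; shifts and
relaxation rates are local per residue and nucleus, with R1 shared across
states and R2 fitted per state. Populations are parameterized through a
softmax so the simplex constraint holds by construction; rates and
relaxation rates are fitted on a log scale.

Numerical choices that matter in practice:

* **Data-driven starts.** Chemical shifts initialize from dip positions
  (local minima of lightly smoothed profiles, with a noise-scaled depth
  threshold so a 1–2% intermediate dip is not discarded); exchange rates
  initialize from saturation-transfer dip depths via `depth ~ k * Tex`.
* **Staged fitting.** Three-state fits are seeded from a quick two-state
  N/D prefit — the standard practice for sparse intermediates, and the
  difference between robust convergence and a compensation minimum in our
  experience with this likelihood surface.
* **Bound-escape restarts.** A parameter pinned at a box bound after
  convergence (typically a minor-state R2 absorbing a misplaced dip) is
  re-seeded from its start value and the descent repeated, at most twice.
* **Multistart.** Five seeded perturbed restarts by default, tie-broken by
  lowest chi-square. Non-convergence is flagged on the result, not raised.
* **Uncertainties** come from the inverse-Hessian (Gauss-Newton `J'J`)
  covariance at the optimum, delta-transformed to the natural scale.

Model selection uses the Gaussian-likelihood statistics with constant terms
dropped: `BIC = chi2 + k log n`, `AIC = chi2 + 2 k`, ranking by BIC with a
stable sort. Between-temperature linkage is deliberately absent (per-
temperature populations and rates), mirroring per-temperature fitting
practice; a van't Hoff-constrained variant would be a modelling extension,
not a drop-in.

The multi-temperature two-state fit (`fitTwoStateThermal`) shares shifts
across temperatures by default — the generator draws a single shift pair
per residue, and sharing is what makes low- and high-population ends of the
melting curve identifiable. Each temperature is first fitted on its own and
those results seed the combined fit.

# The synthetic generator

The generator is the package's stand-in for the study's raw spectra, which
are not publicly deposited. Its defaults *are* the study conditions:

* Triangular N/I/D fixtures for the three beta-domain reporter residues at
  35 °C with `p_I = 0.006`, `kex(N-I) = 27.7 s^-1`, `kex(I-D) = 94.3 s^-1`,
  the printed A42 15N intermediate shift (131.4 ppm) and the printed amide
  1H shift pairs (A42 6.90/9.70, I56 9.37/6.61, T59 8.06/6.14 ppm), and a
  native-state 15N R2 of 10 s^-1.
* Values the study does not print are frozen arbitrary fixture constants,
  flagged `"fixture"` in the object and never presented as published:
  `p_N = p_D = 0.497` (equal at the tertiary melting midpoint),
  `kex(N-D) = 5 s^-1` (slow, HSQC-resolved regime), the unprinted 15N
  N/D shifts and D-state 1H shifts, all R1 values, and the I/D-state R2.
* Acquisition grids follow the published settings: 15N CEST at B1 = 15 and
  60 Hz (16.4 T: 80 offsets, 102 to 132 ppm in 0.38 ppm steps, Tex 0.4 s;
  grids for 11.7/18.8/22.3 T are available), CPMG with Tcp = 40 ms and 20
  pulsing frequencies from 25 to 1000 Hz. The amide 1H CEST grid is not
  printed; the package uses 5.5–10.6 ppm in 0.06 ppm steps at 950 MHz,
  B1 = 60 Hz, Tex 0.3 s.
* Noise is Gaussian: sigma = 0.005 intensity-ratio units for CEST and
  0.3 s^-1 for CPMG, chosen so a 0.6% state sits near the practical
  detection limit. Identical seeds give byte-identical datasets.

What the generator does **not** emulate: H/D-exchange artifact dips, B1
inhomogeneity, off-resonance pulse imperfections, anti-phase detection of
the 1H experiments, and temperature-dependent shifts. Passing tests
therefore demonstrate correctness of the inference machinery under the
stated noise model, not robustness to every spectrometer artifact in real
data.

One bookkeeping discrepancy is documented rather than resolved: the
population-ratio free-energy difference `-RT log(p_D/p_I)` at 308 K is
about -2.7 kcal/mol, while the printed I-D value is -3.06 kcal/mol; with
near-equal N/D populations the printed N-I value (2.7) and I-D value
cannot both be population ratios at the same temperature.
`freeEnergyDifferences()` implements the population-ratio definition.

# Ensemble geometry

All coordinates are in Angstrom; published values quoted in nm (0.75 nm,
1.2 nm) are converted once at the pair-list boundary.

* **Q (fraction of native contacts):** heavy-atom pairs within 4.5 A in
  the native frame between residues more than 3 apart in sequence, each
  scored `1 / (1 + exp(beta (r - lambda r0)))` with `beta = 5 A^-1`,
  `lambda = 1.5`.
* **Ratchet CV:** all heavy-atom pairs with atom-index separation > 35
  (boundary exclusive, indices within the heavy-atom list) and native
  distance <= 12 A; `CV = sum (C_ij - C_ij^native)^2` with the rational
  switching function `C = (1 - x^6)/(1 - x^10)`, `x = r / 7.5 A`, evaluated
  in the factored geometric-series form so the removable singularity at
  `x = 1` evaluates exactly to 0.6.
* **Bias:** `kappa/2 (rho - rho_m)^2` when `rho > rho_m`, else zero, with
  `rho = (CV - CV_target)^2` and `rho_m` its running minimum. The published
  form is labelled a force but has the dimensions of a potential; the
  package treats it as a potential and derives Cartesian forces by the
  chain rule (`-kappa (rho - rho_m) grad rho`). The published all-atom
  force constant (1e-9 kJ/mol) implies CV-dependent units and is not
  adopted for the toy; kappa is configurable.
* **Contact maps:** residues in contact iff any heavy-atom pair < 5.0 A.
* **Hydrogen bonds:** H...acceptor < 2.5 A and donor-H...acceptor
  angle > 120 degrees; acceptors default to all N/O atoms.
* **Amide-pi:** H...ring-COM < 4.5 A; ring-normal/H->COM angle < 54.7
  degrees in the acute convention `min(theta, 180 - theta)` (the ring face
  has no sign); N-H...COM angle > 120 degrees; and the proton engaged in no
  conventional hydrogen bond to a non-aromatic acceptor. Trp contributes
  its 5- and 6-ring independently; His rings are included by default and
  switchable, since their inclusion in the published statistics is
  unstated. Ring normals come from the smallest singular vector of the
  centred member coordinates.
* **Clustering:** GROMOS greedy neighbour-count clustering on CA RMSD with
  a 5 A cutoff; ties in the neighbour count break to the lowest frame
  index for determinism.
* **Landscapes:** 2-D histogram over (CA-RMSD, Q), Gaussian-smoothed in
  bin units (sigma = 2) *before* the logarithm — smoothing after the log
  would let single-sample bins carve spurious basins — then
  `F = -RT log(H / max H)` at 350 K (the rMD production temperature), empty
  bins +Inf. Basins are 4-connected components of `{F < 11 kJ/mol}`
  excluding the component holding the global minimum.
* **SASA:** Shrake-Rupley with 960 golden-spiral points and a 1.4 A probe.
* **Native-state criterion:** superposed CA RMSD <= 3.0 A, boundary
  inclusive.

# The toy rMD demonstration

The coarse-grained fixture is a 30-bead helix-hairpin Go model: stiff 1-2
bonds, softer 1-3 harmonics standing in for angle terms, 12-10 wells at
native contacts, generic r^-12 repulsion elsewhere. The native geometry is
the global minimum by construction (verified against seeded perturbations
in the tests). Dynamics are overdamped Langevin (Euler-Maruyama) — the
published NPT machinery is out of scope and the ratchet contract is
integrator-agnostic. The CV reuses the same pair-list and switching-
function code path with the index-separation threshold rescaled to the
bead chain (> 5).

Unfolding runs high-temperature dynamics until Q < 0.1 (the published
threshold for "completely unfolded"); with `lambda = 1.5` the persistent
short-range contacts keep Q near 0.15 at moderate temperatures, so the
default unfolding temperature is high (kT = 15 in model units). Refolding
uses kT = 0.7, a 40,000-step budget, and kappa = 0.2 on the toy CV scale —
documented as non-transferable to any all-atom setting. Under these
conditions biased trajectories reach the native basin routinely while
unbiased ones essentially never do within the budget, which is the
qualitative contract the method rests on.

# Problem sizes

The package's own test and acceptance runs use: the full three-residue
study dataset (two-B1 15N CEST on the 16.4 and 22.3 T grids, amide 1H CEST, CPMG;
both observed peaks; 2,556 points, 47 parameters) for the headline
triangular fit; single-residue reduced-grid datasets for the fast unit
tests and for the ten-replicate topology-selection experiment; 20
trajectories per arm for the ratchet contract; 20,000 samples for the
landscape tests; 1,000 random scenes for the geometry brute-force
comparison. These sizes were chosen so each experiment answers its
question at desk scale.

# Interfaces

Profiles travel as a TSV dialect (exact header, tab-separated, '#'
comments; see `writeProfiles`), structures as multi-model PDB through
`readPdbEnsemble`/`writePdbEnsemble` (parsing via bio3d), and fit results
as structured JSON reports (`writeFitReport`). Temperatures are Kelvin
internally; frame indices are 1-based in R convention and residue numbers
follow the PDB. The exported functions, the generators and the acceptance
script together form the package's reproducible-run surface; there is no
shell dispatcher, as every documented workflow is an R call.

# Known limitations

The fitting engine assumes Gaussian independent noise with known sigma;
correlated baseline errors in real spectra would require a noise model the
generator does not emulate. The 1H CEST treatment ignores anti-phase
pathways, homonuclear couplings and water exchange. The Shrake-Rupley and
clustering implementations are O(n^2) and meant for desk-scale ensembles,
not microsecond trajectories. The toy rMD model demonstrates the ratchet
logic, not protein energetics; none of its constants transfer to all-atom
force fields.
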
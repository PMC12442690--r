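Package: foldex
Title: Chemical-Exchange NMR Fitting and Structural Ensemble Analysis of
    Sparse Protein Folding Intermediates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and global fitting of CEST, CPMG
    relaxation-dispersion and R1rho NMR profiles for multi-state chemical
    exchange via Bloch-McConnell evolution, with exchange-topology model
    selection (chi-square, BIC, AIC) aimed at sparsely populated folding
    intermediates such as the amyloidogenic intermediate of human lysozyme
    I59T. Includes a seeded synthetic-data generator for all experiment
    types, structure-ensemble analyses (fraction of native contacts,
    ratchet-and-pawl collective variable and bias, contact maps, hydrogen
    bond and amide-pi detection, GROMOS clustering, RMSF, radius of
    gyration, Shrake-Rupley SASA, free-energy landscapes with basin
    extraction) over multi-model PDB ensembles, and a coarse-grained toy
    demonstration of ratchet-and-pawl biased Langevin dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'foldex-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'structure.R'
    'geometry.R'
    'cluster-landscape.R'
    'nucleus.R'
    'rate-matrix.R'
    'simulate.R'
    'fit-global.R'
    'schemes.R'
    'fixtures.R'
    'fit-misc.R'
    'hbonds.R'
    'io-profiles.R'
    'sasa.R'
    'toy.R'
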
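Package: nmrdyn
Title: Chemical-Exchange NMR Dynamics and Ensemble Geometry for SH2 Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting of backbone 15N chemical-exchange NMR data
    for conformational-dynamics studies of SH2 domains and similar small protein
    domains. Provides Bloch-McConnell propagators for two-state and linear
    three-state exchange, CEST and constant-time CPMG relaxation-dispersion
    observables with a Carver-Richards closed-form cross-check, per-residue and
    global (grouped) exchange fitting including CEST-constrained three-state
    CPMG analysis, minor-state chemical-shift reconstruction, fast backbone
    relaxation analysis (R1, R2, heteronuclear NOE, R2/R1 flagging),
    fast-exchange chemical-shift-perturbation titration fitting and
    slow-exchange peak-volume population quantitation, and zipped/unzipped
    beta-sheet classification of multi-model structure ensembles. A seeded
    synthetic-data generator reproduces every input format so each stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
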
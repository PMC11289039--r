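Package: aplysiahill
Title: Hill-Type Muscle Model and Characterization Pipeline for the
    Aplysia I1/I3 Retractor Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Implements a Hill-type muscle model of the I1/I3 retractor
    muscle complex of the sea slug Aplysia californica, together with the
    complete characterization pipeline used to identify it from
    servomotor rig experiments: feature extraction from isometric and
    isokinetic episode traces (force-frequency, length-tension and
    force-velocity protocols), constrained least-squares model fitting,
    series-elastic stiffness estimation, median-individual selection
    across a cohort, forward force simulation by adaptive ODE
    integration, and EMG-envelope-driven validation.  A synthetic
    experiment generator reproduces the rig protocols from a known
    ground-truth model so that every pipeline stage can be tested by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
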
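Package: murilung
Title: Anatomic Forward Modeling of Murine Respiratory Impedance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulation of respiratory input impedance in the mouse
    from an anatomic airway-tree model with constant-phase viscoelastic
    tissue elements.  Builds a hybrid CT/cast branching airway network with
    stochastic per-order geometry, computes its complex input impedance with
    gas-compression and airway-wall shunts, and drives terminal tissue
    heterogeneity from histology-derived empirical distributions (radial
    alveolar counts, elastic fiber thickness) under a family of eight tissue
    models with PEEP-dependent derecruitment.  Includes the companion
    analysis pipeline: impedance spectra from pressure/flow signals,
    constant-phase inverse fitting, quasi-static pressure-volume loop
    statistics, recruitment-fraction estimation, radial-scale and baseline
    elastance estimation, likelihood-ratio model comparison, and a synthetic
    cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
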
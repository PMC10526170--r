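Package: tumorHDC
Title: Hybrid Discrete-Continuum Modelling of Tumoroid Growth and Invasion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth and invasion of glioblastoma tumoroids
    embedded in a collagen matrix that is degraded by externally supplied
    collagenase, using a hybrid discrete-continuum (HDC) model. A
    reaction-diffusion system for cell, nutrient, collagenase and collagen
    concentrations on a polar grid is coupled to a biased random walk for
    individual invading cells whose movement probabilities derive from the
    finite-difference stencil of the cell-flux equation. Includes ring- and
    finger-type invasion quantification, a synthetic chip-experiment
    generator with the observed dose/time significance structure, and a
    calibration harness that recovers the collagen degradation rate from
    invasion-length curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
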
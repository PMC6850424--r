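Package: pbfield
Title: Proton Pencil-Beam Field Characterization and Output-Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing scanned proton pencil-beam fields from
    lateral dose profiles and frame-dose measurements: two-step Gaussian fits
    of the dose core, quadrature decomposition of the scattering-driven width
    growth with depth, full-width-at-x-of-maximum halo metrics with
    misalignment correction, frame factors and field-size factors with
    uncertainty propagation and RMSD agreement statistics, and an analytic
    Gaussian-core field-size-factor forward model with detector volume
    averaging. Includes a phenomenological single-beam dose generator
    (Gaussian core plus linear-exponential nuclear halo, detector disc
    averaging, annular scoring, multiplicative noise) for testing analysis
    pipelines without facility data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
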
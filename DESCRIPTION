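Package: phantomdose
Title: Effective Dose Estimation from Point Dosimetry in Anthropomorphic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for turning point absorbed-dose measurements (e.g. MOSFET
    dosimeters placed in a layered anthropomorphic phantom) into ICRP 103
    equivalent and effective doses. Includes estimators for the irradiated
    tissue mass fractions (red bone marrow, bone surface, skin, muscle,
    lymphatic nodes) from phantom geometry and reference anatomy, type A /
    type B uncertainty propagation by weighted quadrature, a synthetic
    replicate-reading generator for validation, and reporting helpers for
    multi-protocol dose comparisons (dose ratios, mAs-normalised doses,
    background-radiation equivalences).
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
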
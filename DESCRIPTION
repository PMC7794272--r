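Package: acuityfields
Title: Simulation and Analysis of Visual Acuity Performance Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how visual acuity varies with polar angle at
    a fixed eccentricity (visual performance fields). Simulates trial-level
    two-alternative orientation-discrimination data from a ground-truth model
    in which log10 spatial-frequency thresholds and cutoffs change linearly
    with angular distance from the vertical meridian, fits cumulative-normal
    psychometric functions per location by maximum likelihood, inverts them
    at the 75%-correct threshold and 51%-correct cutoff criteria, and
    quantifies the horizontal-vertical anisotropy (HVA) and vertical-meridian
    asymmetry (VMA) with random-intercept linear mixed models, repeated-
    measures ANOVAs, and accuracy-ratio curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
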
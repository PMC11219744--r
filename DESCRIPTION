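Package: pahkin
Title: Urinary PAH Biomarker Toxicokinetics from Spot-Urine Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for urinary polycyclic aromatic
    hydrocarbon (PAH) biomarker toxicokinetics in repeated-measures spot-urine
    studies, as used in occupational biomonitoring of firefighting instructors.
    Provides a void-level synthetic spot-urine generator built on a
    one-compartment first-order absorption/elimination (Bateman) model,
    preprocessing of scheduled and unscheduled voids (pooling, limit-of-detection
    substitution, creatinine adjustment, inclusion filtering), descriptive
    excretion statistics, and per-biomarker elimination half-life estimation via
    a linear mixed-effects exponential-decay model on ln(C - C0) with AR(1)
    residual correlation, fitted by restricted maximum likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
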
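Package: ribotrace
Title: Simulation and Inference of Ribosome Dynamics on Single mRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of single-molecule translation
    imaging of the SunTag/PP7 type, in which nascent-chain fluorescence on
    individual mRNAs reports ribosome number, initiation rate, elongation
    rate, translational state switching, stalling and pausing. Provides a
    deterministic nascent-chain intensity model mapping ribosome positions
    to translation-site fluorescence, an exact event-driven stochastic
    simulator of ribosome traffic with steric exclusion, pause and damage
    sites, two-state translational switching and drug perturbations
    (harringtonine, puromycin, cycloheximide, hippuristanol), estimators
    for every quantity the imaging assay yields (runoff model fitting,
    total-runoff-time elongation rates, initiation-rate flux balance,
    on/off state segmentation, single-ribosome event detection, stall
    classification, polysome buildup analysis, intensity distributions and
    mean-squared-displacement diffusion fits), and a synthetic-data
    generator with calibrated scenario presets so every estimator can be
    validated against ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
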
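Package: strkin
Title: Kinship Likelihood Ratios for Low-Template STR Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Paternity testing on low-template, degraded short tandem repeat
    (STR) profiles. Implements two interpretation workflows side by side: a
    binary consensus workflow (2x consensus profiles from replicate
    amplifications, logistic drop-out calibration, stochastic-threshold
    degradation classification, duo/trio paternity likelihood ratios with a
    coancestry correction and an equal-probability mutation model) and a
    continuous probabilistic-genotyping workflow (gamma peak-height model
    with exponential degradation, backward/forward stutter and exponential
    drop-in, maximum-likelihood estimation, adjusted-loglikelihood model
    selection and probability-probability plot validation), joint over PCR
    replicates and multiple STR kits. A seeded electropherogram simulator
    generates pedigrees and replicate profiles with the same stochastic
    structure, and a study pipeline compares the methods on simulated
    casework cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
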
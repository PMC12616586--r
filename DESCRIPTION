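Package: renoxi
Title: Whole-Organ Renal Oximetry and Metabolic Rate of Oxygen from
    Quantitative MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for whole-organ renal MR
    oximetry under graded isocapnic hypoxia. Generates synthetic cohorts
    and synthetic interleaved T2-prepared / phase-contrast acquisitions,
    fits mono-exponential blood-water T2 decay, converts T2 to venous
    oxygen saturation through a hematocrit-dependent calibration model,
    quantifies venous blood flow rate from velocity maps, computes
    unilateral and bilateral renal metabolic rate of oxygen via Fick's
    Principle with first-order and Monte-Carlo uncertainty propagation,
    and reproduces the repeated-measures ANOVA / Bonferroni analysis of
    hypoxia-challenge experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
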
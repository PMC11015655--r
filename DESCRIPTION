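Package: menarchemr
Title: Triangulated Causal Inference for Pubertal Timing and Adolescent
    Mental Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, simulation-driven pipeline for triangulating the
    effect of age at menarche on adolescent mental health outcomes:
    covariate-adjusted observational regression, one-sample Mendelian
    randomisation by two-stage least squares (with a logistic second
    stage for diagnoses), two-sample summary-data Mendelian
    randomisation with a battery of pleiotropy-robust estimators
    (inverse-variance weighted, MR-Egger, weighted median, contamination
    mixture, MR-PRESSO) and multivariable models, negative-control
    outcome tests, pre-registered equivalence testing against a smallest
    effect size of interest, and Monte-Carlo power analysis. Because the
    motivating cohort data are access-restricted, the package ships a
    synthetic cohort generator that reproduces the study's data
    structure (a weighted allele-score instrument, right-censored
    exposure, skewed symptom scales, rare diagnoses, confounding and
    selective attrition) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
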
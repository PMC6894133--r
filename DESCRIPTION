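Package: hecohort
Title: Privacy-Preserving Detection of Exceptional Cancer Treatment
    Responders with Homomorphic Encryption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates longitudinal oncology cohorts with a small fraction of
    exceptionally long-surviving patients, and analyses them while every
    patient record stays encrypted under a from-scratch implementation of the
    Fan-Vercauteren (FV) somewhat-homomorphic encryption scheme over
    Z_q[X]/(X^n+1). Supports encrypted monthly counting of exceptional
    responders, encrypted total drug exposure (weight times dose, summed over
    monthly visits), parameter selection from a security-standard table with
    an empirical multiplicative-depth certificate, and the supporting
    noncentral chi-squared power analysis for cohort sizing. Cohorts, result
    curves and timing logs are tibbles; a small command-line interface ties
    simulation, key generation, encrypted analysis and reporting together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
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
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
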
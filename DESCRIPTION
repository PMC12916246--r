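Package: cvreact
Title: Hippocampal Cerebrovascular Reactivity from CO2-Challenge BOLD fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of cerebrovascular reactivity (CVR) measured
    with a 5% CO2 inhalation challenge during BOLD fMRI, modelled on the
    two-wave Heart and Brain Study design. Processes breath-by-breath
    capnometry into end-tidal CO2 series, builds normalized regressors,
    estimates CVR in %BOLD/mmHg by ordinary least squares with polynomial
    drift terms, derives cross-scanner standardized change scores for grey
    matter volumes and diffusion metrics, log-transforms white matter
    hyperintensity burden, and fits the covariate-adjusted association suite
    with within-family Benjamini-Hochberg false-discovery-rate correction and
    Cohen's f-squared effect sizes. A synthetic-data generator emulates the
    gas paradigm, capnometry, BOLD signal model and cohort structure with
    known ground truth so every stage is testable without access-controlled
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
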
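Package: bmgrowth
Title: Growth-Exponent Analysis of Brain Metastases After Stereotactic
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discriminates radiation necrosis from progressive disease in
    brain metastases using the growth dynamics of the contrast-enhancing
    lesion volume across three consecutive MRI follow-ups. Implements exact
    identification of the Von Bertalanffy power-law growth model
    dV/dt = alpha * V^beta from three increasing dated volumes, two-point
    instantaneous growth rates, a Monte-Carlo volume-perturbation robustness
    screen for the fitted exponent, nonparametric group comparison with
    ROC/AUC classification and operating-point selection, a calibrated
    synthetic-cohort generator, and a reproducible end-to-end pipeline with
    delimited-text and JSON input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
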
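Package: ocmm
Title: Oral C-Peptide Minimal Model with Bayesian Kinetic Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and Bayesian maximum-a-posteriori identification
    of the oral C-peptide minimal model (OCMM) of insulin secretion, with the
    Van Cauter population model for C-peptide kinetics, regularized estimation
    of the glucose input derivative, beta-cell responsivity indices, a
    synthetic-cohort generator emulating post-gastric-bypass hypoglycemia, and
    an in-silico parameter-recovery study comparing identification approaches
    that fix, re-estimate, or re-prior the C-peptide kinetic parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Matrix,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
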
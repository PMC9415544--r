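Package: tobramipd
Title: Model-Informed Precision Dosing of Once-Daily Tobramycin in Adult Cystic Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Bayesian therapeutic drug monitoring workflow for once-daily
    intravenous tobramycin in adults with cystic fibrosis: closed-form
    two-compartment infusion kinetics with covariate-linked parameters
    (central volume scaled by body weight, elimination linear in
    Cockcroft-Gault creatinine clearance), discrete nonparametric Bayesian
    estimation from peak and trough samples with below-quantification
    substitution and a hybrid range-expansion fit, standardised-peak and
    24-h trough prediction, target-driven once-daily dose recommendation on
    a 25-mg grid, cohort-level target-attainment and safety analytics, and
    a synthetic cohort generator emulating the reference adult population.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
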
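Package: bayesrar
Title: Bayesian Response-Adaptive Randomization for Multi-Arm Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Engine for running and simulating Bayesian response-adaptive
    randomization in multi-arm comparative-effectiveness trials with a
    three-category longitudinal outcome (quit; on drug and efficacious; on
    drug and not efficacious). Provides conjugate Dirichlet-multinomial
    posterior updating, a utility combining tolerability and efficacy,
    multiple imputation of final outcomes from interim visits via
    conditional transition models, information-weighted allocation
    probabilities, success and loser stopping rules, allocation-table
    management in the delete-unassigned-and-append style used by electronic
    data capture systems, and a virtual-trial simulator for estimating
    operating characteristics (type I error, power, expected sample size,
    allocation shares, duration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
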
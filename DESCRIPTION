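Package: sertmipd
Title: Model-Informed Precision Dosing of Sertraline in Pediatric
    Major Depressive Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-pharmacokinetic analysis and initial-dose
    optimization of sertraline in pediatric major depressive disorder.
    Provides a one-compartment first-order-absorption structural model
    with closed-form steady-state predictions, a population model with
    allometric weight scaling and a zopiclone drug-drug-interaction
    covariate, nonlinear mixed-effects estimation (FOCE-I and Laplace)
    with stepwise covariate selection by objective-function-value
    criteria, bootstrap and visual-predictive-check model qualification,
    Monte Carlo probability-of-target-attainment simulation against the
    10-150 ng/mL therapeutic trough window, and a synthetic
    therapeutic-drug-monitoring cohort generator for sparse pre-dose
    sampling designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
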
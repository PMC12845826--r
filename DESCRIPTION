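Package: pafkit
Title: Attributable-Fraction Calculus and Synthetic-Cohort Validation for
    Comparative Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form population-attributable fractions (Levin's formula),
    multiplicative joint PAFs, potential impact fractions for prevalence-reduction
    scenarios, a calibrated synthetic-cohort simulator that validates the closed
    forms by counterfactual exposure elimination, and probabilistic (Monte Carlo)
    and one-way sensitivity analysis over relative risks and exposure prevalences.
    Ships a worked risk-factor table for prostate cancer among men aged 50 years
    and older in the Middle East and North Africa (MENA) region, together with a
    synthetic table generator for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
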
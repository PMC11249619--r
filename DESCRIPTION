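Package: sibcontrol
Title: Measurement Error and False Familial Confounding in Sibling
    Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulation framework for sibling and co-twin
    control designs with classical measurement error in the exposure.
    Generates sibling-pair (or k-sibling) data in which a truly causal
    exposure-outcome effect operates with no familial confounding,
    degrades the exposure with normally distributed error at a chosen
    reliability, and produces single-item ordinal or aggregated ordinal
    outcomes via a latent-threshold model. Fits uncontrolled and
    sibling-control ordered probit and random-intercept linear models,
    standardizes probit coefficients on the latent response scale, and
    summarizes attenuation of the causal estimate, the p-value
    distribution of the family-mean exposure coefficient, the implied
    risk of falsely concluding that familial confounding exists, and
    power to detect the attenuated causal effect. Closed-form expected
    slopes for the continuous-outcome case are included as analytic
    references.
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
    lme4,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
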
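Package: latentmed
Title: Latent-Outcome Mediation Analysis by Structural Equation Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits structural equation models combining a latent
    health-related quality-of-life outcome measured by multiple indicators
    with treatment and mediator regressions, by maximum-likelihood
    covariance-structure estimation (RAM formulation, nlminb optimizer).
    Provides standardized solutions, fit indices (chi-square/df, CFI, RMSEA,
    SRMR, AIC), product-of-coefficients mediation decomposition with
    delta-method standard errors and percent contributions, backward
    mediator elimination, and a seeded synthetic-trial generator emulating a
    2:1 randomized migraine-prevention trial for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
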
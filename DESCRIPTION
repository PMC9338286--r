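Package: stimchoice
Title: Probit Analysis of Sequential-Offer Choice Under Microstimulation
Version: 0.1.0
Authors@R: person("stimchoice", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of two-juice sequential-offer choice
    sessions with interleaved electrical microstimulation. Provides a
    seeded generator of counterbalanced choice sessions, maximum-likelihood
    probit fitting of five psychometric models (presentation-order bias,
    side bias, and three choice-hysteresis variants), derivation of the
    relative value rho, sigmoid steepness eta and bias coefficients,
    per-session stimON/stimOFF contrasts, population-level paired tests
    with exact Wilcoxon signed-rank p values, bivariate confidence
    ellipses, a 3-SD outlier rule, and rectified, max-normalized effect
    sizes across stimulation-window by current-level conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
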
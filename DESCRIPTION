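Package: emaxpop
Title: Population Steepness of Sigmoid Emax Concentration-Effect Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how inter-individual variability (IIV) in the
    parameters of the sigmoid Emax (Hill) concentration-effect model flattens
    the population-averaged concentration-effect relationship. Provides the
    closed-form population-steepness approximation
    gamma* = 1.7 / sqrt((1.7/gamma)^2 + omega_C50 + 1.25*omega_gamma/gamma^2
    + 2.5*omega_C50*omega_gamma/gamma), the Monte Carlo procedure that
    calibrates its constants, simulators for binary (quantal) and continuous
    concentration-response trials with log-normal IIV, and maximum-likelihood
    estimators (naive pooling, and nonlinear mixed effects via a
    Laplace-approximated marginal likelihood) to validate the approximation
    in replication studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), pracma, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
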
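Package: richtitr
Title: Richards-Function Modelling of Serum Antibody Titration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling serum antibody titration with the Richards
    (generalized logistic) function and its two-variable extension for dual
    antigen-antibody titration surfaces. Provides closed-form evaluation of the
    logistic, Richards and Gompertz family in several parametrizations, fitting
    of single and double Richards models to log-scale fluorescence data by
    Levenberg-Marquardt nonlinear least squares with data-driven starting
    values and by Bayesian Markov chain Monte Carlo with weakly informative
    priors, a thermodynamic interpretation layer converting fitted asymmetry
    parameters into excess enthalpy and entropy and the thermodynamic titer,
    and a synthetic-data generator for dual-titration designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    coda,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
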
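Package: softsensr
Title: Hybrid Soft Sensors for Soluble Compounds in Fed-Batch E. coli Cultivations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates concentrations of soluble compounds (acetate, lactate,
    glutamate, glutamine, isoleucine) in fed-batch Escherichia coli
    cultivations from off-gas measurements. Latent physiological states
    (biomass, specific growth rate, average and cumulative cell age) are
    derived from the oxygen uptake rate through a strain-specific oxygen
    balance; recurrent (LSTM) soft sensors are trained over enumerated input
    groups; predictions are combined by RMSE-weighted ensemble averaging with
    the committee size selected by Shannon-entropy information gain. A
    mechanistic fed-batch simulator (Monod growth with overflow-metabolism
    acetate) generates synthetic campaigns so the whole pipeline can be
    exercised without proprietary cultivation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
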
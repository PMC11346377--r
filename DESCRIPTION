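Package: streamnet
Title: Spatial Linear Models on Dendritic Stream Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits Gaussian spatial linear models to data observed on dendritic
    stream (river) networks. Provides a directed network representation with
    additive function values, asymmetric hydrologic distance matrices with
    flow-connected/flow-unconnected classification, tail-up, tail-down and
    Euclidean covariance components, restricted maximum likelihood (REML) and
    maximum likelihood estimation, universal kriging prediction with 95%
    prediction intervals, leave-one-out cross-validation, Gaussian simulation
    on the network, and a seeded synthetic-network generator so that every
    analysis is reproducible without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    foreign
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
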
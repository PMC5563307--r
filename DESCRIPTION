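Package: adtfnet
Title: Time-Varying Directed EEG Networks and Epileptogenic Zone
    Localization from Inter-Ictal Discharges
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of inter-ictal scalp EEG discharges with time-varying
    directed networks. Tracks time-varying multivariate autoregressive
    (MVAR) coefficients with a Kalman filter, converts them to the adaptive
    directed transfer function (ADTF), builds phase-randomization surrogate
    null distributions to threshold connectivity into binary dynamic
    networks, and localizes the epileptogenic-zone electrode as the
    earliest non-background channel with sustained strong outflow in the
    binarized out-degree matrix. Includes EDF/EDF+ input and output, a
    synthetic EEG generator with planted discharge sources for validation,
    and a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
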
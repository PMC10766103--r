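Package: bisqus
Title: Bispectral Energy Feature Maps and Multi-Map Deep Classification for Ultrasound RF Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative ultrasound tissue characterization from raw
    radiofrequency (RF) frames via higher-order spectral analysis. Estimates
    third-order cumulants and bispectra of RF signal segments, subdivides the
    non-redundant bifrequency domain into low/mid/high-frequency bands, and
    assembles per-frame bispectral energy feature maps (BS_S1, BS_S2, BS_S3,
    BS_A). Provides inter-map comparison statistics (histograms, mutual
    information, RMSE), a B-mode envelope stand-in, a four-branch
    weight-sharing convolutional classifier with gated feature-map attention
    and a cosine-similarity constraint loss, a seeded nonlinear RF phantom
    simulator for fully synthetic end-to-end experiments, and evaluation
    metrics (confusion-matrix ratios, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
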
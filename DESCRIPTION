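Package: k2mse
Title: Multiscale Entropy and the Bi-Scaling Law for Fractal Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Multiscale entropy (MSE) analysis built on the correlation
    entropy K2(epsilon) of Grassberger-Procaccia type, for fractal
    (1/f-type) time series.  Provides exact-in-distribution simulation of
    fractional Gaussian noise by circulant embedding, spectral synthesis of
    1/f^alpha noise, block-average coarse-graining with its variance
    scaling law, fast correlation-integral and sample-entropy estimation
    over scale grids, fits of the bi-scaling law
    K2^(bs)(eps) ~ (H - 1) ln bs - ln eps with a derived Hurst-parameter
    estimator, the Shannon-Kolmogorov (rate-distortion) entropy of
    stationary Gaussian processes via the Kolmogorov water-filling
    formula, and feature extraction (smallest resolvable scale, linear-fit
    error, K2 at selected scales) for discriminating physiological
    recordings such as heart-rate-variability and EEG series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
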
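Package: transcol
Title: Collocation-Based Error Estimation and Merging of Transpiration Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates random error variances, sensitivities and error
    cross-correlations (ECC) of three or more collocated transpiration
    (or other geophysical flux) products with triple collocation, extended
    collocation and the extended double instrumental variable (EIVD)
    method; converts the fitted error models into MSE-optimal merging
    weights that honour non-zero ECC; produces merged series and gridded
    netCDF products; benchmarks the result against flux-tower
    transpiration partitioned with the underlying water-use efficiency
    (uWUE) method; and scores estimates with RMSE, ubRMSE, MAE, relative
    bias, modified Kling-Gupta efficiency, Pearson correlation,
    Theil-Sen trends and Mann-Kendall significance. A synthetic-data
    generator with prescribed affine biases and error covariance makes
    every stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    ncdf4,
    quantreg,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
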
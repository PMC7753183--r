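Package: mvconn
Title: Regularized Multivariate Functional Connectivity for ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-region multivariate functional connectivity from
    region-of-interest (ROI) fMRI time series. Implements ridge-regression
    connectivity (RIDGEC) with a fixed penalty, random-forest connectivity
    (RANFORC) with a constrained, fully deterministic forest, and the
    weighted global brain connectivity (GBC) baseline with thresholded
    variants. Includes second-level coefficient and variable-importance
    maps, Fisher r-to-z transformation, group-level statistics (two-sample
    t-tests, per-region linear models with covariates, Benjamini-Hochberg
    FDR), a synthetic-data generator for ROI cohorts with temporal
    autocorrelation and planted age/sex effects, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
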
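Package: memdecode
Title: Time-Resolved MEG Decoding and Representational Geometry of Image Memorability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved multivariate pattern analysis of epoched
    magnetoencephalography (MEG) data, built around the question of whether
    highly memorable images carry a distinct perceptual neural signature.
    Provides an HDF5 epochs container, epoch-domain preprocessing (baseline
    removal, zero-phase low-pass filtering, amplitude-based trial rejection,
    PCA-based blink-artifact projection), pseudo-trial sub-averaging, pairwise
    linear-SVM decoding into time-resolved representational dissimilarity
    matrices (RDMs), representational similarity analysis against categorical
    and dispersion hypothesis geometries, temporal generalization, and
    nonparametric group inference (cluster-size permutation tests, bootstrap
    peak-latency intervals, exact Wilcoxon signed-rank, signal-detection
    d-prime). A synthetic-cohort generator with controlled representational
    geometry drives recovery and calibration studies at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rhdf5,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    ggplot2,
    withr
Config/testthat/edition: 3
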
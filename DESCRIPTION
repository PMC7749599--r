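Package: cpcmorph
Title: Coefficients of Probability Change for Longitudinal Tissue Probability Maps
Version: 0.1.0
Authors@R:
    person("cpcmorph", "maintainers", email = "maintainers@cpcmorph.org",
           role = c("aut", "cre"))
Description: Voxel-neighborhood estimation of coefficients of probability
    change (CPC): a non-negative 4x4 transfer matrix mapping tissue
    existence probabilities (gray matter, white matter, cerebrospinal
    fluid, background) at baseline to those at follow-up, fitted per
    voxel by thresholded, renormalized non-negative least squares over
    3x3x3 neighborhoods. Includes a parametric longitudinal atrophy
    phantom generator, volume-of-interest averaging of CPC elements,
    rank-based ROC group discrimination, and cross-validated
    PCA-reduced classification (support vector machine, random forest,
    gradient boosting) of diagnostic groups. Reads and writes NIfTI-1
    volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    quadprog,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
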
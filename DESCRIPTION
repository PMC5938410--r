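Package: mlsmap
Title: Multiple-Lesion Symptom Mapping with Support Vector Regression
Version: 0.1.0
Authors@R:
    person("mlsmap", "developers", email = "mlsmap@example.org",
           role = c("aut", "cre"))
Description: Voxel-based lesion-symptom mapping for cohorts in which two
    lesion types co-occur in the same brains (e.g. acute ischemic lesions
    and white matter hyperintensities). Implements mass-univariate VLSM
    with permutation-based familywise-error correction, multivariate
    lesion-symptom mapping by epsilon-insensitive support vector
    regression (SVR-LSM), and its multiple-lesion extension (SVR-MLSM)
    in which every voxel contributes one indicator column per lesion
    type. Includes volume-control strategies (voxelwise 1/sqrt(volume)
    normalization and regressing lesion volumes out of the behavior
    score), leave-one-out cross-validated hyperparameter training,
    permutation inference on voxel weights, significant-cluster
    extraction with atlas overlap reports, significant-cluster
    volume-of-interest (SVOI) behavior prediction ladders, and a
    synthetic two-lesion cohort simulator with planted strategic
    regions for method validation. Reads and writes NIfTI-1 lesion
    masks and statistical maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
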
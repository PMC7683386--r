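Package: benmap
Title: Voxelwise Brain Entropy Mapping and Group Inference for
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes voxelwise brain entropy (Sample Entropy) maps from
    4D resting-state fMRI images and carries an entropy study through to
    group inference: subject-level motion quality control (framewise
    displacement, translation and rotation limits), motion nuisance
    regression and Gaussian smoothing, mass-univariate ANOVA/regression
    with max-statistic permutation family-wise error control, Monte-Carlo
    cluster-extent thresholds, and quadratic stage-trajectory fitting of
    entropy across the Alzheimer's disease continuum (HC, SMC, EMCI,
    LMCI, AD). Includes a synthetic cohort generator that modulates voxel
    entropy through AR(1) autocorrelation so the whole pipeline is
    testable without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
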
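Package: prsmvpa
Title: Multivariate Pattern Regression of Brain Structure on Polygenic
    Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline linking polygenic risk scores (PRS) to
    multivariate grey-matter patterns. Builds PRS by p-value-informed LD
    clumping and thresholding with allelic scoring, extracts masked voxel
    features from NIfTI grey-matter maps with Gaussian smoothing, fits
    sparse Bayesian relevance vector regression (RVR) under leave-one-out
    or k-fold cross-validation with confound residualization inside the
    folds, assesses significance by label permutation with
    Benjamini-Hochberg false-discovery-rate control, performs voxelwise
    GLM regression with max-statistic permutation family-wise-error
    control, and summarizes model weight maps by atlas region. Ships a
    seeded synthetic imaging-genetics cohort generator (block-LD
    genotypes, discovery summary statistics, smooth voxel maps carrying a
    plantable distributed signal, covariates) for validation and power
    studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
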
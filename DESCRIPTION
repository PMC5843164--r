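Package: gaitpatterns
Title: Gait Phenotyping by Multivariate Dynamic Time Warping, Random
    Forests and Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies whole, time-normalized gait cycles into sagittal
    flexion patterns by hierarchical clustering of multivariate dynamic
    time warping (DTW) dissimilarities, explains the patterns with
    interpretable spatio-temporal and kinematic parameters through
    permutation-importance random forests, and relates patterns and
    parameters to clinical features with linear mixed models,
    log-linear models, robust MM-estimator regressions and
    bias-corrected-and-accelerated bootstrap contrasts. Includes a
    synthetic gait-cohort generator with known ground truth for
    validating every stage of the pipeline, and plain-text exchange
    formats for cycles, events and clinical records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    MASS,
    randomForest,
    pROC,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    boot,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
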
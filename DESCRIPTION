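Package: cortexplain
Title: Explainable Convolutional Classification of Spatiotemporal Cortical
    Current-Density Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates two-group cohorts of trial-wise cortical current-density
    time series on a registered spherical surface, converts them into
    standardized Mollweide-projected 120x120x16 spatiotemporal volumes, trains
    2d/3d convolutional neural network classifiers with a leave-one-subject-out
    pretraining / fine-tuning transfer-learning protocol, and localizes the
    discriminative spatiotemporal features with layer-wise relevance
    propagation (LRP-0 / LRP-gamma), GradCAM, guided backpropagation and
    guided GradCAM. Includes a weighted minimum-norm inverse stage, heatmap
    aggregation and region-of-interest analyses, and the group/correlation
    statistics used to characterize cohorts (pooled-SD Cohen's d, two-sample
    t tests from summary statistics, Fisher's exact test, one-tailed Pearson
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    signal,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
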
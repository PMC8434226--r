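Package: wtss
Title: Wavelet-Based Discovery of Time-Series Shapelets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Unsupervised discovery of variable-length candidate shapelets in
    labeled univariate time series using continuous wavelet transform
    scalograms. Per-scale power rows are standardized, thresholded and
    dichotomized; maximal runs of high-energy samples are clipped from the
    original series to form a candidate pool. The pool is reduced either by
    global alignment kernel k-means with cluster center-lines or by a
    variance filter, and minimum sliding-window Euclidean distances to the
    final shapelets feed multiclass logistic or gradient-boosted-tree
    classifiers. A gradient-based learned-shapelet comparator, synthetic
    generators with planted ground truth, and confusion-matrix, F1,
    feature-importance and partial-dependence reporting are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    nnet,
    xgboost,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
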
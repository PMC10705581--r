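Package: postclust
Title: Selective Inference for Feature Mean Differences After Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests for a difference in the mean of a single feature between two
    clusters that were estimated from the same data, controlling the selective
    type I error rate in finite samples under a multivariate Gaussian model with
    known (or plug-in) feature covariance. The selective p-value is the tail
    probability of a univariate Gaussian truncated to the set of perturbations
    of the observed data that leave the clustering unchanged; this truncation
    set is computed exactly for hierarchical clustering (single, average,
    centroid and Ward linkage on squared Euclidean distances) and for Lloyd's
    k-means algorithm by intersecting the solution sets of quadratic
    inequalities. Includes the naive two-sample Z-test baseline, plug-in
    covariance estimators, Benjamini-Hochberg adjustment across features,
    synthetic-data generators and simulation experiments for type I error,
    conditional power and detection probability, and count-matrix
    preprocessing conventions for single-cell RNA-seq data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    withr,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
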
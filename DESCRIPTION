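Package: sbmclust
Title: Grid- and Graph-Based Density Clustering for Spike Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic grid-based density clustering for spike-sorting
    feature spaces with imbalanced, overlapping clusters. Implements the
    Space Breakdown Method (SBM), which partitions the feature space into
    equal chunks, finds local density maxima and grows clusters by
    breadth-first descent, and its improved variant (ISBM), which stores
    only occupied chunks in a sparse chunk graph and adapts the number of
    partitions per dimension to each feature's variance. Also provides the
    Spike Cluster Score, an external validation metric tolerant of
    overclustering and invariant to noise-labelled points, synthetic
    generators for imbalanced overlapping Gaussian mixtures, and a small
    benchmark harness comparing against classical clustering algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
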
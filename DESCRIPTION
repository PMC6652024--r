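Package: iodetect
Title: Sparse-Cluster Detection of Implausible Observations in EHR Laboratory Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised screening of electronic health record (EHR) laboratory
    and vital-sign values for biologically implausible entries. Observation
    series are shuffled, partitioned into folds, standardized and cubed to
    emphasize distribution tails, clustered with a hybrid hierarchical K-means
    (HK-means) procedure whose cluster number is approximated by iterative
    subsampling with BIC model selection, and clusters whose population falls
    at or below a sparsity ratio alpha of the fold are flagged as implausible.
    Includes conventional anomaly-detection baselines (standard-deviation and
    Mahalanobis-distance thresholding), a confusion-matrix evaluation harness
    against silver-standard plausibility intervals, and a synthetic lab-data
    generator with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
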
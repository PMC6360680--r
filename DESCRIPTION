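Package: BCRange
Title: Biplot Correlation Range Feature Selection for Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Group-wise feature selection for mass-spectrometry intensity
    tables with a binary phenotype. Decomposes the centered data matrix into
    one response-orthogonal and one predictive component (direct orthogonal
    signal correction followed by first-component partial least squares),
    interprets the resulting biplot loading arrows through their weighted
    covariance/correlation geometry, and selects features whose arrows fall
    in the angular wedge subtended by a group's confidence ellipse of scores,
    survive a top-fraction magnitude cut, and pass a univariate logistic
    weak-separability filter. Also provides Benjamini-Hochberg and
    Benjamini-Yekutieli false-discovery-rate selectors and an OPLS-coupled
    statistical total correlation spectroscopy selector as baselines, a
    layered synthetic-data generator for benchmarking, a replicated
    benchmark harness, and preprocessing utilities for LC-MS feature tables
    (duplicate averaging, missing-value filtering, zero imputation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'baselines.R'
    'bcrSelect.R'
    'benchmark.R'
    'decomposition.R'
    'featureTable.R'
    'simdata.R'
    'tableio.R'
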
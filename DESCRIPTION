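Package: stabmark
Title: Stability-Selected Biomarker Panels from High-Dimensional Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies candidate biomarkers from high-dimensional omics
    feature tables with a binary clinical outcome. Provides quality-controlled
    preprocessing (duplicate-probe merging, probe-to-gene collapsing by
    maximal mean expression, near-zero-variance filtering, median imputation,
    autoscaling), iterated LASSO and Elastic-Net feature selection over
    repeated stratified train/test splits with inner cross-validated penalty
    optimisation, frequency-based stability ranking, exhaustive combinatorial
    evaluation of candidate panels by resampled test-set ROC AUC, and an
    empirical permuted-label AUC null distribution for unbiased performance
    assessment. A synthetic-data generator with planted informative features
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse,
    withr
Config/testthat/edition: 3
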
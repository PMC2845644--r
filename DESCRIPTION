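Package: sagat
Title: Knowledge-Augmented Differential Expression via SVD Eigengene Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies differentially expressed genes by combining a small
    expression dataset with coexpression structure learned from a large
    compendium of prior microarray knowledge. The compendium is decomposed
    into eigengenes by singular value decomposition; a novel dataset is
    projected into eigengene space by pseudoinverse projection and scored
    with a variance-moderated t-like statistic (the SAGAT score) whose
    standard error pools empirical-Bayes moderated eigengene variances, so
    coexpressed genes share variance information. Includes a synthetic
    compendium/dataset generator with block-covariance modules, coexpression
    module detection on binarized covariance matrices with a permutation
    null, ROC-based evaluation utilities (AUC, TPR at fixed FPR, gold
    standards from highly replicated data, effective-number-of-arrays
    standard curves), and rank-products meta-analysis across platforms with
    permutation-based per-family error rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
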
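Package: fprf
Title: Fuzzy-Pattern Constrained Random Forests for Feature Selection in
    Multi-Class Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step feature selection and prioritization for multi-class
    gene expression matrices. Expression values are fuzzified per gene into
    Low/Medium/High linguistic labels via Gaussian and sigmoidal membership
    functions; class-specific fuzzy patterns collect the genes whose modal
    label is highly frequent within a class. A random forest of unbiased
    (association-test based) classification trees, whose per-node candidate
    features are drawn one per fuzzy pattern, then ranks the candidates by
    out-of-bag permutation accuracy importance. Includes a stratified
    bootstrap evaluation harness with multi-class F-score and G-mean metrics,
    a self-consistency stability statistic for selected feature lists, and a
    synthetic data generator with planted class-specific features.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
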
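Package: fabscreen
Title: Detecting Fabricated Samples in Omics Tables with Digit-Frequency
    Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forensic screening of quantitative omics tables for fabricated
    samples. Simulates copy-number-alteration-like cohorts with segmental
    structure, fabricates fake samples by three mechanisms (per-gene uniform
    random draws, resampling with replacement, and iterative random-forest
    imputation), transforms samples into Benford-like decimal digit-frequency
    features, and benchmarks classifier families (gradient boosting, naive
    Bayes, random forest, k-nearest neighbours, support vector machines) at
    separating real from fabricated samples, including feature-downsampling
    robustness studies and diagnostics (PCA, digit distributions, gene-pair
    correlation preservation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    e1071,
    class,
    xgboost,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
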
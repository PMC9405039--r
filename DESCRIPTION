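Package: ckdboost
Title: Cost-Sensitive AdaBoost with Information-Gain Feature Selection for
    Imbalanced Clinical Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting chronic kidney disease (and similar binary
    outcomes) from imbalanced, mixed-type clinical tables. Implements the full
    pipeline: schema-driven preprocessing (nominal encoding, mean imputation,
    selective min-max scaling), entropy-based information-gain feature ranking
    with a standard-deviation selection threshold, conventional AdaBoost and a
    cost-sensitive AdaBoost variant whose weight update uses class-wise error
    rates and four-case cost factors, confusion-matrix metrics with ROC/AUC,
    a stratified k-fold cross-validation harness, and a synthetic-data
    generator emulating the 24-attribute UCI CKD schema for reproducible
    benchmarking without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rpart,
    stats,
    utils,
    foreign,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
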
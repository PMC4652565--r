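Package: xplatclass
Title: Platform-Independent Multi-Class Expression Classification via
    Unsupervised Discretization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated machine-learning pipeline for transferring
    isoform-level gene-expression classifiers across measurement platforms
    (for example exon-array to RNA-seq). Continuous log2 fold-change
    profiles against a platform-matched normal reference are discretized
    per feature by equal-width binning, equal-frequency binning or 1-D
    k-means; features are ranked by coefficient of variation, multiclass
    SVM-RFE or random-forest backward elimination with out-of-bag error;
    and four multi-class classifiers (linear one-vs-one SVM, random
    forest, naive Bayes and nearest shrunken centroids) are benchmarked
    over representation, selector and feature-count grids for same-platform
    and cross-platform designs. Includes a paired-platform synthetic data
    generator with known subtype structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    randomForest,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
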
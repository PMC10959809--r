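Package: reopairs
Title: Rank-Based miRNA-Pair Biomarker Discovery from Serum Expression Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and evaluation of qualitative serum miRNA biomarkers
    built on within-sample relative expression orderings (REOs). Provides
    sample quality control (k-nearest-neighbour imputation, correlation-based
    outlier removal, duplicate screening), screening of stable and reversed
    miRNA pairs (Fisher exact test with Benjamini-Hochberg correction and the
    degree-of-reversal statistic), a hypergeometric model for differential
    miRNA identification, a seeded greedy majority-voting pair classifier,
    LASSO-regression and random-forest comparator models, standard
    classification metrics, and a synthetic multi-batch cohort generator with
    planted pair reversals for ground-truth validation. All pair statistics
    and classifiers depend only on within-sample orderings and are therefore
    invariant to monotone per-sample distortions such as batch effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    randomForest,
    Rtsne,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Classification, DifferentialExpression, FeatureExtraction,
    Transcriptomics, miRNA
RoxygenNote: 7.3.3
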
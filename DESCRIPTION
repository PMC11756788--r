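Package: irchrom
Title: Chromatin-Aware Prediction and Interpretation of Intron Retention
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds labeled DNase-hypersensitive-site (DHS) sequence datasets for
    intron retention (IR), trains convolutional sequence classifiers and
    chromatin-target based classifiers to predict IR, and interprets the fitted
    models via integrated-gradients attribution, hot-spot extraction, JASPAR
    motif scanning and a motif enrichment statistic, together with logistic
    weight rankings of chromatin targets. Includes a synthetic-data module that
    generates genomes, retained-intron annotations, motif-planted DHS sequences
    and chromatin-target matrices with known ground truth so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    optparse
Config/testthat/edition: 3
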
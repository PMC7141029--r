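Package: cfpromoter
Title: Promoter Coverage Profiling of Cell-Free DNA and Discretized
    Logistic Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for nucleosome-footprint analysis of cell-free DNA
    (cfDNA) in promoter regions. Builds strand-aware primary transcription
    start site (pTSS, -1 kb..+1 kb) windows from transcript annotation,
    counts aligned cfDNA fragments per window, normalizes to RPKM, and
    computes TSS metagene depth profiles for gene sets. Identifies
    promoters with differential coverage between case and control samples
    (Wilcoxon rank-sum test with Benjamini-Hochberg FDR), and trains
    discretized stepwise logistic classifiers: per-promoter cutoffs chosen
    by balanced accuracy, strict binarization, bidirectional AIC stepwise
    selection, leave-one-out cross-validation, and ROC evaluation with
    DeLong confidence intervals and paired AUC comparison. Ships the
    published 12-gene macrosomia classifier and a cfDNA fragment simulator
    with a two-tissue (placenta/maternal blood) nucleosome-depletion model
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    withr,
    generics,
    stats,
    tools,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
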
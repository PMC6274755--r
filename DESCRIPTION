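Package: ernanet
Title: Causal Transcription Regulatory Network Inference from Enhancer RNA
    Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers causal transcription-factor (TF) to target-gene
    interactions from CAGE-style expression data by using enhancer RNA
    (eRNA) activity as a causal anchor. For each trio (enhancer E, TF A,
    candidate target B) five likelihood-ratio tests are evaluated on
    rank-normalized expression, converted to exact p-values through a
    transformed-Beta null family, and combined into an empirical-Bayes
    posterior causality score. Each enhancer can be treated as a
    continuous or a binary (on/off) anchor, and an adaptive selector
    picks the mode with the strongest primary enhancer-TF linkage.
    Includes the data-processing rules for promoter/enhancer expression
    tables, evaluation utilities (precision-recall, BH-corrected
    hypergeometric enrichment against ChIP-seq or knock-out derived
    target sets), and a seeded generator of CAGE-like synthetic datasets
    with known causal structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
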
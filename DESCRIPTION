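Package: dbdmotif
Title: Discovering DNA-Binding-Domain Motifs from Differential ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies binding motifs of individual DNA-binding domains of a
    transcription factor by contrasting wild-type and domain-mutant ChIP-seq
    experiments. Peaks significantly stronger in the wild type are labelled
    against preserved peaks with a negative-binomial differential test, a small
    convolutional network is trained to predict the label from sequence, the
    network is interpreted with Rescale-rule contribution scores, and
    high-attribution seqlets are clustered into aggregate motifs. Downstream
    tooling covers motif trimming, mega-motif construction, PWM scanning with
    exact background p-values, SELEX read-pool enrichment scoring, peak-overlap
    partition comparisons and peak-strength association tests, plus a seeded
    synthetic-data generator that makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
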
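Package: atacouple
Title: Differential Chromatin Accessibility, Expression Detection and
    Motif Co-Occurrence Analysis for Two-Population ATAC/RNA Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing chromatin accessibility and
    gene expression between two FACS-sorted cell populations profiled by
    ATAC-seq and RNA-seq. Provides replicate peak merging into consensus
    sets, qualitative exclusive/shared peak classification, quantitative
    differential accessibility and expression via a moderated negative
    binomial Wald test, an intergenic-window based detection threshold for
    expressed-gene calling, nearest-TSS peak annotation, joint
    accessibility-expression coupling classification, PWM scanning with
    single-motif and order-3 motif-combination co-occurrence enrichment
    against random genomic background, and a fully deterministic
    synthetic-data generator with ground-truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
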
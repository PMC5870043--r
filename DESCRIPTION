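Package: aneuploidr
Title: Dosage, Cis/Trans and Compensation Analysis of Aneuploid Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream transcriptome analysis for chromosome-substitution and
    alien-addition aneuploids in a two-subgenome (A/C) background. Starting
    from a gene-level count matrix, the package computes FPKM, identifies
    dosage-altered chromosomes from chromosome-wide expression shifts against
    a euploid reference, calls differentially expressed genes at a twofold /
    BH q < 0.05 decision rule, partitions them into cis (on copy-number
    altered chromosomes) and trans effects with directional chi-square bias
    statistics, and classifies one-dose genes on a monosomic chromosome into
    dosage-compensation classes against the halved-expression null. A
    negative-binomial simulator with known karyotype, trans-effect and
    compensation ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    ggplot2,
    rlang,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
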
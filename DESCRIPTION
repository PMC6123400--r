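Package: spermdyn
Title: Staged Single-Cell Transcriptome Analysis of Mouse Spermatogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for staged single-cell RNA-seq of mouse
    spermatogenesis across twenty ordered germ-cell stages. Implements cell
    quality control, ERCC spike-in size-factor normalization, TPM and log
    transforms, differential expression with an explicit log-scale average
    difference formula and Benjamini-Hochberg adjustment, the meiotic sex
    chromosome inactivation (MSCI) / postmeiotic sex chromatin (PMSC) gene
    classification scheme, a five-situation alternative-splicing transition
    classifier over merged stage samples, splicing-regulator and surface-marker
    screens, correlation-threshold transcription-factor co-expression networks,
    and a silhouette-based test of intercellular transcript sharing between
    haploid spermatids. Ships a negative-binomial synthetic-data generator with
    planted ground truth for every downstream analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    igraph,
    cluster,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
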
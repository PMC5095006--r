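Package: scramblex
Title: Circular RNA Detection and Sponge Scoring via a Scrambled Exome Reference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies circular RNA (circRNA) candidates from
    paired-end RNA-seq data by building a scrambled exome: the set of all
    intragenic backsplice (head-to-tail) exon-pair junction sequences derived
    from a genome and its annotation. Read pairs placed on this reference are
    classified as junctional or supportive evidence for a backsplice and
    candidates are called under configurable count thresholds, with randomized
    and flipped-exon negative-control references run through the identical
    logic. Includes a lightweight k-mer seed-and-extend paired-end mapper so
    the whole pipeline is testable without an external aligner, a read
    simulator with known truth for sensitivity/precision benchmarking,
    circular-to-linear abundance ratios, FPKM and z-scored log2-CPM
    transforms, an RNase-R-style enrichment comparison, miRNA seed-match
    scanning (8mer, 7mer-m8, 7mer-A1) and the E_circ / Average E_circ
    weighted-expression statistic over circRNA-miRNA-gene networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    generics,
    ggplot2,
    yaml,
    withr,
    stats,
    utils,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    IRanges,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
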
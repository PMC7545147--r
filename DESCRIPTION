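Package: chromactiv
Title: De Novo Chromatin Activation Analysis for Tumor Epigenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for detecting tumor-specific chromatin
    activation from multi-layer epigenomic profiles (six histone-mark ChIP-seq
    peak sets, ATAC-seq, whole-genome bisulfite sequencing and RNA-seq) of
    malignant plasma cells against a panel of normal B-cell populations.
    Identifies regions with stable chromatin across normal B-cell
    differentiation that gain or lose individual marks in myeloma, selects de
    novo H3K27ac-activated regulatory elements, stitches and ranks
    superenhancers, assigns chromatin states and state-transition matrices,
    links activated regions to target genes through topologically associating
    domains and differential expression, detects coregulated adjacent
    coexpressed gene groups, and quantifies motif-anchored CpG hypomethylation.
    Ships a synthetic multi-omics data generator with a planted-truth manifest
    so the full pipeline is testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
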
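Package: riscshift
Title: Simulation-Backed Analysis of RNAi Activity and RBP Co-Binding from PAR-CLIP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic test bed for quantifying miRNA-guided
    repression (RNAi activity) and RNA-binding-protein competition from
    PAR-CLIP-style data. The package simulates a toy transcriptome with planted
    Argonaute (AGO) and FAM120A binding sites, PAR-CLIP reads carrying
    diagnostic T-to-C conversions, miRNA abundance profiles and matched
    differential-expression tables; calls binding-site clusters from conversion
    evidence with a kernel-density signal model; annotates clusters to
    transcript features; applies a 6mer miRNA seed filter; and compares
    log2 fold-change cumulative distributions of occupancy-ranked target bins
    against non-targets, including the stabilization of targets co-bound by a
    competing RBP. Ancillary computations cover TMT interactome enrichment
    filtering, differential-expression thresholding, miRNA fold changes and
    Malthusian growth fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
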
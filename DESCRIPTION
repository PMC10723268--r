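Package: anchorloops
Title: Classification of Chromatin Loop Anchors, TAD Boundaries and
    p300/H3K27me3 Repressive Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of chromatin architecture around
    H3K27ac-independent ("p300-only") regulatory sites. Derives p300-only
    peaks from ChIP-seq peak sets, annotates chromatin-loop anchors and
    TAD boundaries against gene features (promoter, terminator, gene body)
    and histone marks, censuses anchor interaction categories, detects
    head-to-tail TAD-boundary gene pairs, compares gene expression between
    anchor classes with self-contained rank-based tests, and provides
    Hi-C contact-matrix operations (VC_SQRT balancing, virtual 4C
    viewpoint profiles, aggregate peak analysis). Includes a synthetic
    data generator that plants p300-only/H3K27me3 loops, head-to-tail
    boundary gene pairs and promoter-repression expression deficits, with
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
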
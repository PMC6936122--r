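Package: rbpcons
Title: Cross-Species Conservation Analysis of RNA-Binding-Protein Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the cross-species conservation of
    RNA-binding-protein (RBP) binding sites identified by CLIP-seq. Maps 20 bp
    binding sites onto multiz-style multiple-alignment (MAF) blocks and
    computes the percentage of aligned species each site is conserved in,
    builds per-RBP conservation distributions and per-species presence
    matrices, generates random-region conservation nulls, scores the
    similarity of conservation profiles within RBP families against
    tree-derived evolutionary distances, ranks RBP-centric features by
    RReliefF attribute importance, compares conservation across strand-aware
    5'/middle/3' genic thirds, and performs score-weighted permutation
    gene-set enrichment with a corrected p-value. A synthetic-data module
    generates MAF/BED/GMT/tree/feature-table fixtures with planted,
    recoverable structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
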
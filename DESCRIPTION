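Package: rbclust
Title: Detection and Analysis of Clustered RbFox (T)GCATG Binding Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide detection of clustered (T)GCATG RbFox-family
    binding elements on gene sense strands by a seed-and-extend-and-merge
    rule, classification of clusters into genomic-context categories
    (exon, UTR, proximal/distal intron, mixed), integration with CLIP
    peak intervals into gene-level strata, enrichment testing of
    LASR-associated repeat motifs against randomized background
    sequences with chi-square statistics and Benjamini-Hochberg FDR,
    and stratified comparison of isoform log2 fold-change tables.
    Includes a synthetic-data generator producing genome, annotation,
    peak and expression fixtures with known ground truth, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
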
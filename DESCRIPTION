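Package: synteloss
Title: Gene Presence/Absence Inference by Homology Search, Reciprocal
    Best Hits, and Microsynteny
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects gene loss in annotated genomes the way comparative
    studies of agastric (stomach-less) fish established it: a query
    protein is searched against a target genome and transcriptome with a
    seed-and-extend local aligner (Smith-Waterman extension, bit scores,
    Karlin-Altschul E-values), candidate loci are verified by reciprocal
    top-hit search against a multi-species ortholog panel, and calls are
    validated by microsynteny - anchoring the flanking genes of the
    expected locus in the target and scanning the intervening interval
    before an absence is accepted. Includes a synthetic annotated-genome
    generator with ground-truth gene losses, paralog duplications and
    inversions, deterministic gene-neighborhood fixtures, and
    FPKM-based anterior-to-posterior expression-gradient profiling of
    intestinal segment RNA-seq counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
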
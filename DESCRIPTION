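Package: regulonflow
Title: Regulon Reconstruction and Signal-Flow Analysis for Two-Component
    Signaling Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs transcription-factor regulons from perturbation
    RNA-seq expression tables (deletion and depletion contrasts with paired
    replicates), intersects them with ChIP-derived binding sites assigned to
    genes and operons, and quantifies the flow of information through a
    signaling pathway DAG by regulon overlap, normalized to the direct (sink)
    regulon. Infers missing (hidden) inputs at each pathway node, scans
    half-site/spacer consensus binding motifs, and fits growth-corrected
    single-exponential protein-decay curves. Includes a seedable synthetic
    cascade generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
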
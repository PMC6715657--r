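Package: regcons
Title: Comparative Analysis of Transcription Factor Binding Regions and
    Cross-Species Target Conservation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of ChIP-seq binding regions for a
    transcription factor profiled in two tissues of two species.
    Classifies peaks into seven genomic categories relative to gene
    models, scans peak sequences on both strands with position-weight
    matrices including palindromic dimer motifs at a relative-score
    threshold, scores per-base evolutionary conservation in
    summit-centered windows and compares peak sets with a Mann-Whitney
    rank test, calls regulated genes by intersecting cis-regulatory
    peak-to-gene assignments with an FPKM/fold-change/q-value expression
    filter, and measures cross-species conservation of the regulated
    gene sets through an ortholog map. A synthetic-data generator
    produces complete two-species desk-scale datasets with every planted
    property recorded in a ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: ChIPSeq, Annotation, SequenceMatching, Epigenetics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
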
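Package: stereoflow
Title: Spatial Transcriptomics Read Positioning, Annotation and Expression
    Matrix Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for lattice-barcoded spatial
    transcriptomics data. Reads carrying a 25-base coordinate barcode (CID)
    and a 10-base molecular barcode (MID) are restored to chip coordinates by
    exact or single-substitution matching against a chip mask, filtered,
    annotated against gene models (exonic/intronic/intergenic with strand
    concordance), MID-corrected by count-ordered Hamming merging, and
    aggregated into a binnable spatial gene-expression matrix. Downstream
    stages extract the tissue-covered region from the expression heatmap by
    grayscale segmentation and compute sequencing-saturation and
    median-gene curves under subsampling. A synthetic-data generator
    produces chips, reads, alignments and ground truth so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
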
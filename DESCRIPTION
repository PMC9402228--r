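Package: imprintr
Title: Parent-of-Origin Expression Bias Classification and Nuclear
    Compartment Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies genome-wide parent-of-origin bias in transcription
    (RNA-seq) and chromatin-mark enrichment (CUT&RUN) from allele-resolved
    read counts: per-replicate exact binomial tests against Mendelian
    expression, Bonferroni correction, a five-category maternal-ratio
    scheme, G-test replicate-heterogeneity filtering and count pooling.
    Includes 1x genome-coverage normalization and fractional peak-gene
    overlap association for chromatin profiling, an adaptive-threshold 3D
    nucleus segmenter with plateau detection, k-means heterochromatin-foci
    segmentation with size filtering, compartment-overlap statistics, and
    synthetic-data generators (beta-binomial allele counts, multi-channel
    nucleus images) with ground truth for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
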
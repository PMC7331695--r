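Package: liquidSCNA
Title: Copy Number Profiling and Tissue-of-Origin Classification for
    Circulating Tumor Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Somatic copy number alteration (SCNA) analysis for few-cell
    liquid-biopsy samples profiled by low-coverage whole-genome sequencing.
    Provides binned read-count normalization, loess correction of GC and
    mappability amplification bias, circular binary segmentation, ploidy
    fitting to integer copy states, gene- and cytoband-level SCNA call
    matrices, tumor versus circulating-tumor-cell concordance statistics
    and clustering, and a random-forest tumor tissue-of-origin classifier
    built on cytoband SCNA values, a chromosomal instability score and a
    two-dimensional t-SNE embedding. A seeded synthetic-data generator
    emulates clonally related tumor/CTC genomes, GC-biased low-pass read
    counts and multi-class SCNA cohorts so the full pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    randomForest,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
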
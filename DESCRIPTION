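Package: chromtss
Title: Chromatin-State Analysis Around Globally Defined Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of chromatin-mark configurations around CAGE-defined robust
    transcription start site clusters (RTSSs). Classifies RTSSs by expression and
    genomic location, builds oriented binned ChIP-seq profiles around RTSS anchors,
    clusters profile shapes per mark with Pearson-correlation-distance k-means and
    meta-clusters RTSSs on their correlation-coefficient features, selects poised
    (repressed but active-mark-bearing) RTSSs with a dependent-correlations test,
    and validates groupings via neighbourhood expression correlation, CpG-island
    enrichment with Monte-Carlo testing, and PCA on term-gene matrices. Includes a
    synthetic-data generator with planted ground truth so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
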
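Package: exofootprint
Title: Motif-Anchored Footprint Profiling of ChIP-exo Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds strand-specific 5'-end coverage footprint profiles of
    ChIP-exo signal around transcription-factor motif matches inside bound
    regions. Provides JASPAR/TRANSFAC motif parsing, log-odds scanning with
    exact score-distribution p-value thresholds, degenerate-consensus
    (constrained-position) matching, permuted-motif null controls with
    empirical coverage p-values and motif ranking, subsampling and profile
    differencing, k-means clustering of per-site footprints, and a synthetic
    ChIP-exo read simulator with known cross-link geometry so every stage of
    the analysis can be validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    rlang,
    ggplot2,
    jsonlite,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
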
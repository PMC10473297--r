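Package: cofluct
Title: Hierarchical Clustering of Peak Co-Fluctuation Patterns in Edge Time Series
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes functional connectivity into edge time series
    (framewise products of z-scored parcel signals), segments the global
    co-fluctuation amplitude (RMS) into trough-to-trough event segments,
    extracts peak co-fluctuation patterns, measures their pairwise
    similarity with Lin's concordance, and groups them with a recursive,
    significance-gated modularity-maximization algorithm into a nested
    multiscale hierarchy.  Includes downstream characterization (cluster
    centroids, leading eigenmodes, system projections, bipartition
    templates), split-half data-requirement curves, and a synthetic
    state-switching generator with circular-shift surrogates so every
    stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
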
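Package: overlapMPS
Title: Multivariate Pattern Similarity and Decoding for Partially
    Overlapping Spatial Environments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for multivariate pattern-similarity (MPS) and decoding
    analyses of memory retrieval across partially overlapping spatial
    environments. Encodes a three-city store-layout design (shared and
    unique landmarks, spatial-distance and temporal-interval triads),
    simulates single-trial voxel patterns and BOLD time series with
    planted reinstatement, pattern-separation/repulsion, spatial-schema
    and environment-identity signals, estimates single-trial and run-level
    t-statistic patterns with least-squares-separate GLMs, filters voxels
    by temporal signal-to-noise ratio, and implements template-based
    holistic-reinstatement similarity, between-city similarity with
    sharing-class pair rules, leave-one-city-out support-vector
    regression/classification, searchlight mapping, and partial-correlation
    modulation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: StatisticalMethod, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
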
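Package: scnaging
Title: Lifespan Brain Volumetrics and Structural Covariance Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Region-of-interest brain volumetrics with covariate-adjusted
    group contrasts, Y-maze spontaneous-alternation scoring and
    brain-behavior association, and group-wise structural covariance
    network (SCN) construction with permutation-based comparison of
    node-level and global graph measures across density thresholds,
    including Walktrap community detection and provincial/connector hub
    cartography. Ships a synthetic-cohort generator with planted group
    effects, block covariance structure and trial-level behavior so the
    full pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
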
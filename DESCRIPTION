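Package: exprsearch
Title: Content-Based Nearest-Neighbor Search for Gene Expression Profiles
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A content-based search engine for gene expression databases.
    Expression profiles are optionally reduced by principal component
    analysis and indexed in a vantage-point tree, a metric-space binary
    search tree that supports exact nearest-neighbor and top-K retrieval
    with triangle-inequality pruning under any user-supplied metric.
    Includes readers and writers for a simple HDF5 expression dialect,
    a versioned persisted index, a brute-force oracle and KD-tree
    comparator with hardware-independent distance-evaluation benchmarks,
    a deterministic generator of clustered synthetic expression data,
    and a build/search command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rhdf5,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
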
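Package: tsegnet
Title: Network-Based Segmentation of Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments multivariate time series (e.g. time-resolved gene
    expression) by reconstructing correlation networks on candidate time
    segments, measuring distances between the networks of consecutive
    segments through local, local-global and global network properties,
    and finding the optimal segmentation as a maximum-weight path in a
    directed acyclic graph, optionally penalized for the number of
    breakpoints or the segment-length distribution. Includes a
    dependence-preserving permutation test for correlation thresholds,
    a synthetic ARMA benchmark generator with planted breakpoints, and
    command-line entry points for simulation and segmentation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
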
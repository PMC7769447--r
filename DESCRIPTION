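Package: patchConnect
Title: Graph-Theoretic Connectivity and Prioritization of Habitat Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds dispersal-threshold graphs from polygon habitat layers
    (urban grasslands and similar fragmented habitat) and computes landscape
    connectivity descriptors: number of links (NL), number of components (NC),
    the area-covering component count, and the Integral Index of Connectivity
    (IIC). Per-patch importance (dIIC) is obtained by node removal and
    partitioned exactly into its intrapatch, flux and connector fractions,
    supporting patch prioritization across dispersal distance thresholds.
    Includes Conefor-compatible node/connection file input and output, a
    synthetic landscape generator (truncated lognormal patch sizes, river-like
    barrier strip, center-peaked district population gradient), per-district
    green-space-per-capita analysis, and a reproducible threshold-sweep
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    polyclip,
    igraph,
    foreign,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
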
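Package: cgbiclust
Title: Clustered Groups Biclustering of Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@cgbiclust.org",
           role = c("aut", "cre"))
Description: Finds groups of co-expressed genes together with the conditions
    of co-expression (biclusters) in real-valued expression matrices using the
    clustered-groups (CG) approach: a threshold-free discretization that
    selects, for every gene, the conditions above the largest gap in its
    sorted absolute normalized profile; exact grouping of identical signed
    profiles; three checkpoint tests on the cluster correlation matrix that
    decide which clusters merge; an optional construction of gene-overlapping
    biclusters; and a selection cutoff on a combined size-correlation score
    calibrated against pure-noise random matrices.  Includes generators for
    implanted-bicluster synthetic data and Jaccard-based recovery/relevance
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
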
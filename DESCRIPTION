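Package: bimodularity
Title: Directed Community Detection via Bimodularity and Spectral Edge Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community detection for directed graphs based on the bimodularity
    index, which scores pairs of sending and receiving node partitions against
    a directed configuration-model null. Provides the directed modularity
    matrix B = A - k_out k_in^T / m, its singular value decomposition as the
    spectral relaxation that maximizes bimodularity, edge embeddings built
    from the leading singular vector pairs, and k-means clustering of edges
    to extract bicommunities (paired sending/receiving communities) with
    per-cluster scores and node roles. Includes directed stochastic-block-model
    generators (block-cycle and general block-direction structures) for
    validation, generic edge-list and adjacency readers, and a small
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
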
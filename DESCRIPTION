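Package: sdembed
Title: Multidimensional Hyperbolic Embedding of Networks with the Geometric
    Soft Configuration Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Embeds undirected networks into (D+1)-dimensional hyperbolic
    space under the S^D geometric soft configuration model. Infers per-node
    hidden degrees and positions on a D-sphere together with the global
    inverse temperature beta, using model-corrected Laplacian Eigenmaps for
    initialization and maximum-likelihood refinement of coordinates. Includes
    an S^D generator for synthetic ground-truth networks (power-law hidden
    degrees with natural cutoff, optional spherical-cap communities) and an
    evaluation suite (greedy routing, geometric community concentration,
    Procrustes coordinate alignment, connection-probability curves, partition
    quality) used to validate embeddings and select a network's intrinsic
    dimension.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
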
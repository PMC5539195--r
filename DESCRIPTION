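Package: physarumnet
Title: Slime-Mould-Inspired Transport Network Formation over Terrain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-agent simulation of a virtual Physarum polycephalum
    plasmodium on a 2D lattice whose sensory behaviour is modulated by a
    greyscale terrain heightfield, together with extraction of the emergent
    transport network (skeletonization and Steiner-node resolution into
    region-region adjacency matrices) and a weighted "Physarum graph"
    statistics layer over replicate experiments (threshold transforms,
    connectivity and planarity reports, edge-count statistics and
    mean-degree rankings).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
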
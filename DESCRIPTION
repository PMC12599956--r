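Package: giantcell
Title: Spatial Patterning Analysis of Giant Cells in Plant Epidermis
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the spatial arrangement of giant (highly
    endoreduplicated) pavement cells in segmented plant epidermal tissue.
    Provides a data model for labeled rasters and cell-adjacency graphs,
    shape- and size-preserving tissue randomization null models with
    resampling-based clustering statistics, a synthetic tissue generator
    with planted spatial patterns, a stochastic cell-autonomous simulator
    of giant-cell fate commitment in a growing polygonal tissue, and
    cell-size-distribution comparison via 1-D Wasserstein distances with
    permutation tests and principal-coordinate embedding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    igraph,
    png,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
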
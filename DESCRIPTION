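Package: clonemetrics
Title: Morphometrics of Cell Clones in Epithelial Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the geometry of genetically marked cell clones in
    packed epithelia: interface circularity (isoperimetric quotient),
    apical-area statistics inside and outside clones, cell-mixing index,
    contact length, clone-area recovery, and interfacial junction-intensity
    enrichment. Includes a synthetic-epithelium generator (centroidal
    power-diagram tessellation with controllable clone compaction, boundary
    smoothing, and dispersal), watershed-based cell and clone segmentation
    of membrane/marker image channels, cell-adjacency-graph clone objects,
    and rank-sum statistical reporting with box-plot summaries and
    cell-area heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    grDevices,
    tools,
    utils,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
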
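Package: edisom
Title: Supra-Hexagonal Self-Organizing Map Clustering of Time-Course
    Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for gene expression time courses measured
    against a single control condition, as arises in staged (e.g.
    escalating-dose immunotherapy) designs. Applies a detectability floor
    and a stage-wise fold-change regulation filter, fits a supra-hexagonal
    self-organizing map with a Gaussian neighbourhood kernel to the
    filtered log2 fold-change profiles, partitions the trained map into
    gene clusters from the topology of the codebook (seed units at local
    minima of the neighbour-distance surface), renders component-plane
    presentations of each treatment stage, and performs per-cluster
    hypergeometric term enrichment with Benjamini-Hochberg adjustment.
    Includes a synthetic-data generator that plants five canonical
    temporal expression archetypes for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
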
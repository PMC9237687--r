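Package: pangraphr
Title: Pangenome Variation Graphs: GFA I/O, Editing, Metrics, Layout and Liftover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-memory, node-centric model of pangenome variation graphs
    V = (N, E, P) with delta-encoded adjacency and doubly-linked path steps,
    plus the standard interrogation and transformation operations used on
    such graphs: lossless GFAv1 reading and writing with PanSN-aware path
    names, a native serialized format, structural editing (chop, unchop,
    extract, explode, squeeze, prune), summary statistics and node
    depth/degree tracks, topological and path-guided stochastic gradient
    descent (PG-SGD) node ordering in 1D and 2D with a stress diagnostic,
    path-jaccard context mapping for coordinate liftover between embedded
    genomes, untangling of collapsed loci into PAF mappings with copy-number
    recovery, and 1D binned visualization with name, position, strand and
    depth color modalities. Deterministic synthetic graph generators (linear
    chains, bubbles, copy-number variants, collapsed repeats) with planted
    ground truth support testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2,
    igraph,
    Biostrings,
    png
Config/testthat/edition: 3
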
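Package: sbmlpatterns
Title: Frequent Structural Pattern Mining in SBML Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers frequent structural patterns in biochemical reaction
    networks encoded in the Systems Biology Markup Language (SBML). Models are
    parsed into labelled bipartite digraphs of species and reaction nodes with
    reactant, modifier and product role edges; a gSpan-style frequent connected
    subgraph miner with minimum and maximum support thresholds enumerates all
    frequent patterns up to a size cap; patterns can be rendered as SBGN
    process-description style diagrams, exported as Cypher graph-database
    queries, and counted per model into a feature matrix of injective embedding
    counts. A structural mode and an SBO-annotation-aware mode are supported,
    together with a synthetic corpus generator with planted patterns for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    xml2,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
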
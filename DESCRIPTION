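Package: netflex
Title: Temporal Flexibility of Bipartite Ecological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how the architecture of bipartite ecological
    interaction networks (e.g. predator-prey, plant-pollinator) changes
    through time. Implements the additive decomposition of network
    dissimilarity (Sorensen or Bray-Curtis) into an interaction-rewiring
    component and a species-turnover component, under both the
    subtraction-based and the common-denominator partitioning frameworks;
    dissimilarity between each temporal realization and the aggregated
    meta-network; leave-one-species-out indices that identify "network
    coordinator" species with high potential contributions to network
    flexibility; per-link flexibility scores contrasted with static edge
    betweenness; standard vertex centralities on the meta-network; and a
    seeded generator of synthetic temporal bipartite interaction series
    with planted coordinator species for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    optparse,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
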
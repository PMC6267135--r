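Package: spreadnet
Title: Influence Spreading Model for Network Centrality, Cohesion and
    Community Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the probability that influence initiated at one node of a
    directed or undirected network reaches every other node by a given time, by
    enumerating self-avoiding paths (or bounded walks), organising them as a
    prefix trie and combining them with an explicit treatment of shared path
    prefixes under a Poisson temporal spreading model. On top of the resulting
    influence spreading matrix the package provides closeness centrality,
    network cohesion, removal-based betweenness, geodesic baseline measures,
    and community detection by local maximisation of a two-faction
    intra-influence objective, together with Monte-Carlo and pairwise-algebra
    validation oracles and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
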
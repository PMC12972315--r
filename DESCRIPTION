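Package: pathmult
Title: Path Multiplicity, Community Structure and Tribal Scale-Free Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies path multiplicity -- the number of equidistant shortest
    paths between node pairs -- in undirected networks and relates it to
    community structure. Implements a simultaneous all-pairs shortest-path
    counting algorithm based on adjacency-matrix powers, the path multiplicity
    index (PMI) and its Erdos-Renyi-normalized relative form (RPMI), the
    quadrant count ratio association statistic, deterministic leading-eigenvector
    modularity community detection with single-vertex refinement, a
    target-oriented greedy edge-rewiring optimizer under fixed size, density and
    connectivity, and the Tribal Scale-Free (TSF) generative model with planted
    communities, together with reference generators (ER, NW, BA, CBA, ring
    lattice) and experiment drivers for density sweeps, corpus summaries,
    rewiring trajectories and model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    tools,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
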
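# Fixture builders shared across the suite. All graphs are igraph objects;
# randomized builders take an explicit seed.

path_graph <- function(n) igraph::make_ring(n, circular = FALSE)
cycle_graph <- function(n) igraph::make_ring(n)
complete_graph <- function(n) igraph::make_full_graph(n)

# Two K4 cliques joined by a single bridge edge (vertices 1..4 and 5..8).
bridged_cliques <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  igraph::add_edges(g, c(4, 5))
}

# nk cliques of size sz joined in a ring by single edges.
clique_ring <- function(nk = 4, sz = 8) {
  g <- igraph::disjoint_union(lapply(seq_len(nk),
                                     function(i) igraph::make_full_graph(sz)))
  anchors <- (seq_len(nk) - 1L) * sz + 1L
  igraph::add_edges(g, as.vector(rbind(anchors, c(anchors[-1], anchors[1]))))
}

# A random connected graph of one of several topology families, used by the
# oracle-equivalence property tests.
random_connected_graph <- function(seed) {
  withr::with_seed(seed, {
    kind <- sample(c("er", "tree", "cycle", "bipartite", "planted"), 1)
    g <- switch(kind,
      er = {
        n <- sample(5:40, 1)
        giant_component(igraph::sample_gnp(n, runif(1, log(n) / n, 0.5)))
      },
      tree = igraph::sample_tree(sample(5:40, 1)),
      cycle = cycle_graph(sample(4:40, 1)),
      bipartite = {
        a <- sample(2:6, 1); b <- sample(2:8, 1)
        igraph::make_full_bipartite_graph(a, b)
      },
      planted = {
        nc <- sample(2:4, 1)
        tsf_graph(nc * sample(6:10, 1), nc, intra_degree = 4)$graph
      }
    )
    if (igraph::vcount(g) < 3 || !igraph::is_connected(g)) {
      g <- cycle_graph(6)
    }
    g
  })
}

expect_same_graph <- function(g1, g2) {
  expect_equal(igraph::vcount(g1), igraph::vcount(g2))
  named <- !is.null(igraph::vertex_attr(g1, "name")) &&
    !is.null(igraph::vertex_attr(g2, "name"))
  canon <- function(g) {
    el <- igraph::as_edgelist(g, names = named)
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  expect_equal(canon(g1), canon(g2))
}
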
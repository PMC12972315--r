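# Modularity, spectral splitting, refinement and recursive detection.

# independent brute-force modularity: explicit double sum over all pairs
modularity_bruteforce <- function(g, labels, gamma = 1) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- igraph::degree(g)
  m <- igraph::ecount(g)
  q <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(A))) {
      if (labels[i] == labels[j]) {
        q <- q + A[i, j] - gamma * k[i] * k[j] / (2 * m)
      }
    }
  }
  q / (2 * m)
}

# exhaustive best bipartition over <= 16 nodes
best_bipartition_q <- function(g) {
  n <- igraph::vcount(g)
  best <- -Inf
  for (code in 0:(2^(n - 1) - 1)) {
    lab <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    best <- max(best, modularity_q(g, lab))
  }
  best
}

test_that("modularity matches hand computation and the brute-force sum", {
  g <- bridged_cliques()
  expect_equal(modularity_q(g, rep(1, 8)), 0)

  # split at the bridge: 6 within-edges per clique, 13 edges total,
  # degree sum 13 per side
  q_hand <- 2 * (6 / 13 - (13 / 26)^2)
  expect_equal(modularity_q(g, rep(c(0, 1), each = 4)), q_hand)

  for (seed in 1:8) {
    g <- giant_component(withr::with_seed(seed, igraph::sample_gnp(15, 0.25)))
    lab <- withr::with_seed(seed, sample(3, igraph::vcount(g), replace = TRUE))
    expect_equal(modularity_q(g, lab), modularity_bruteforce(g, lab))
    expect_equal(modularity_q(g, lab),
                 igraph::modularity(g, lab))   # independent implementation
  }
})

test_that("implicit operator equals the dense generalized matrix", {
  for (seed in 1:6) {
    g <- giant_component(withr::with_seed(seed, igraph::sample_gnp(30, 0.15)))
    n <- igraph::vcount(g)
    u <- withr::with_seed(seed, sort(sample(n, max(5, n %/% 2))))
    x <- withr::with_seed(seed + 100, rnorm(length(u)))
    dense <- pathmult:::modularity_submatrix(pathmult:::modularity_ctx(g), u)
    expect_equal(modularity_matvec(g, x, subset = u),
                 as.numeric(dense %*% x), tolerance = 1e-10)
    # rows of the generalized matrix sum to zero
    expect_equal(max(abs(rowSums(dense))), 0, tolerance = 1e-10)
  }
})

test_that("spectral split separates obvious structure and detects indivisibility", {
  # two disjoint K4s: the split must separate the cliques, and the exhaustive
  # oracle confirms it is the best bipartition
  g <- igraph::disjoint_union(complete_graph(4), complete_graph(4))
  sp <- leading_eigenvector_split(g)
  expect_false(sp$indivisible)
  expect_equal(length(unique(sp$s[1:4])), 1)
  expect_equal(length(unique(sp$s[5:8])), 1)
  expect_true(sp$s[1] != sp$s[5])
  expect_equal(modularity_q(g, sp$s), best_bipartition_q(g))

  # K5 and a star: no bipartition improves on the trivial one
  expect_lte(best_bipartition_q(complete_graph(5)), 0)
  expect_equal(detect_communities(complete_graph(5))$n_c, 1)
  star <- igraph::make_star(7, mode = "undirected")
  expect_lte(best_bipartition_q(star), 0)
  expect_equal(detect_communities(star)$n_c, 1)
})

test_that("refinement is monotone and fixes single misassignments", {
  g <- bridged_cliques()
  ideal <- rep(c(1, -1), each = 4)
  expect_identical(kl_refine(g, s = ideal), ideal)

  wrong <- ideal; wrong[4] <- -1
  expect_identical(kl_refine(g, s = wrong), ideal * ifelse(ideal[1] == 1, 1, -1))

  for (seed in 1:10) {
    tg <- tsf_graph(10, 2, intra_degree = 3, seed = seed)
    s0 <- withr::with_seed(seed, sample(c(-1, 1), 10, replace = TRUE))
    if (length(unique(s0)) == 1) s0[1] <- -s0[1]
    s1 <- kl_refine(tg$graph, s = s0)
    expect_gte(modularity_q(tg$graph, s1), modularity_q(tg$graph, s0) - 1e-12)
  }
})

test_that("detection recovers planted clique rings and is deterministic", {
  g <- clique_ring(4, 8)
  part <- detect_communities(g)
  expect_equal(part$n_c, 4)
  expect_equal(length(unique(part$membership[1:8])), 1)
  # matches an independent maximizer's modularity on this easy instance
  ig <- igraph::cluster_louvain(g)
  expect_equal(part$Q, igraph::modularity(g, igraph::membership(ig)),
               tolerance = 1e-6)

  p2 <- detect_communities(g)
  expect_identical(part$membership, p2$membership)

  for (g in list(path_graph(9), complete_graph(6), cycle_graph(12))) {
    expect_identical(detect_communities(g)$membership,
                     detect_communities(g)$membership)
  }
})

test_that("reported Q equals an independent recomputation", {
  for (seed in 1:6) {
    g <- giant_component(withr::with_seed(seed, igraph::sample_gnp(40, 0.1)))
    part <- detect_communities(g)
    expect_equal(part$Q, modularity_q(g, part$membership), tolerance = 1e-10)
    expect_equal(part$Q, modularity_bruteforce(g, part$membership),
                 tolerance = 1e-10)
    expect_equal(sort(unique(part$membership)), seq_len(part$n_c))
    expect_true(part$Q >= -1 && part$Q <= 1)
  }
})

test_that("detection recovers planted TSF communities", {
  for (seed in 1:6) {
    tg <- tsf_graph(160, 8, seed = seed)
    expect_equal(detect_communities(tg$graph)$n_c, 8)
  }
})
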
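# GKK, TSF and reference generators.

test_that("gkk_static hits the requested edge count and validates input", {
  for (seed in 1:5) {
    g <- gkk_static(40, 100, 0.5, seed = seed)
    expect_equal(igraph::vcount(g), 40)
    expect_equal(igraph::ecount(g), 100)
    expect_equal(igraph::count_multiple(g), rep(1, 100))
  }
  expect_error(gkk_static(10, 50, 1.0), "alpha")
  expect_error(gkk_static(10, 100, 0.5), "pairs")
})

test_that("gkk weight exponent maps to the predicted degree exponent", {
  # lambda = (1 + alpha)/alpha: alpha = 0.5 -> 3
  expect_equal((1 + 0.5) / 0.5, 3)
  # Hill/MLE tail estimate on a large draw should sit near 3
  g <- gkk_static(2000, 6000, 0.5, seed = 31)
  deg <- igraph::degree(g)
  kmin <- 6
  tail <- deg[deg >= kmin]
  lambda_hat <- 1 + length(tail) / sum(log(tail / (kmin - 0.5)))
  expect_gt(lambda_hat, 2.3)
  expect_lt(lambda_hat, 3.7)
  # homogeneous limit: alpha = 0 has no comparable heavy tail
  g0 <- gkk_static(2000, 6000, 0, seed = 31)
  expect_lt(max(igraph::degree(g0)), max(deg))
  expect_lt(stats::var(igraph::degree(g0)), stats::var(deg))
})

test_that("tsf draws satisfy the exact structural identities", {
  for (seed in 1:20) {
    nc <- sample(c(2, 4, 8), 1)
    tg <- tsf_graph(120, nc, seed = seed)
    expect_equal(sum(tg$sizes), 120)                      # sizes partition N
    expect_equal(sort(tabulate(tg$membership)), sort(tg$sizes))
    expect_equal(nrow(tg$inter_edges), tg$n_e * (nc - 1)) # inter-edge identity
    expect_equal(igraph::ecount(tg$graph),
                 nrow(tg$intra_edges) + nrow(tg$inter_edges))
    expect_true(igraph::is_connected(tg$graph))
    # intra edges join same-community nodes, inter edges different
    expect_true(all(tg$membership[tg$intra_edges[, 1]] ==
                      tg$membership[tg$intra_edges[, 2]]))
    expect_true(all(tg$membership[tg$inter_edges[, 1]] !=
                      tg$membership[tg$inter_edges[, 2]]))
  }
})

test_that("tsf degenerate and invalid configurations behave", {
  tg <- tsf_graph(50, 1, seed = 3)
  expect_equal(nrow(tg$inter_edges), 0)
  expect_equal(igraph::ecount(tg$graph), nrow(tg$intra_edges))

  expect_error(tsf_graph(10, 8), "sizes below 2")
  expect_error(tsf_graph(40, 4, n_e = 0), "n_e")
})

test_that("tsf is seed-deterministic", {
  a <- tsf_graph(80, 4, seed = 9)
  b <- tsf_graph(80, 4, seed = 9)
  expect_identical(a$membership, b$membership)
  expect_same_graph(a$graph, b$graph)
})

test_that("reference models have their defining structure", {
  expect_same_graph(rrl_graph(12, 2), cycle_graph(12))
  expect_equal(igraph::degree(rrl_graph(20, 4)), rep(4, 20))
  # cycle PMI by hand: C12 has 60 unordered pairs with one route and the 6
  # antipodal pairs with two
  expect_equal(pmi(rrl_graph(12, 2))$phi,
               2 * (60 * 1 + 6 * 2) / (12 * 11))

  expect_identical(pmi(ba_graph(40, 1, seed = 2))$phi, 1)  # tree

  g <- er_graph(30, m = 80, seed = 4)
  expect_equal(igraph::ecount(g), 80)
  expect_identical(igraph::ecount(er_graph(30, m = 80, seed = 4)),
                   igraph::ecount(g))

  nw <- nw_graph(30, 4, n_add = 7, seed = 5)
  expect_equal(igraph::ecount(nw), 30 * 2 + 7)

  cba <- cba_graph(60, 2, p_triad = 0.5, seed = 6)
  expect_equal(igraph::vcount(cba), 60)
  expect_true(igraph::is_connected(cba))
  # triad formation raises clustering over plain BA on average
  cl_cba <- mean(vapply(1:6, function(s)
    igraph::transitivity(cba_graph(80, 3, 0.8, seed = s)), 0))
  cl_ba <- mean(vapply(1:6, function(s)
    igraph::transitivity(ba_graph(80, 3, seed = s)), 0))
  expect_gt(cl_cba, cl_ba)
})

test_that("match_reference reproduces size and near-matches density", {
  ref <- giant_component(er_graph(60, m = 150, seed = 7))
  er <- match_reference(ref, "er", seed = 1)
  expect_equal(igraph::vcount(er), igraph::vcount(ref))
  expect_equal(igraph::ecount(er), igraph::ecount(ref))

  ba <- match_reference(ref, "ba", seed = 1)
  m_per_node <- max(1, round(igraph::ecount(ref) / igraph::vcount(ref)))
  expect_lte(abs(igraph::ecount(ba) - igraph::ecount(ref)),
             m_per_node * igraph::vcount(ba))

  tsf <- match_reference(ref, "tsf", seed = 1, n_c = 4, n_e = 2)
  expect_equal(igraph::vcount(tsf), igraph::vcount(ref))
  expect_lt(abs(edge_density_frac(tsf) - edge_density_frac(ref)) /
              edge_density_frac(ref), 0.05)
})

test_that("tsf graphs dominate density-matched baselines in path multiplicity", {
  tg <- tsf_graph(180, 10, seed = 12)
  phi_tsf <- pmi(tg$graph)$phi
  phi_er <- mean(vapply(1:4, function(s)
    pmi(giant_component(match_reference(tg$graph, "er", seed = s)))$phi, 0))
  phi_ba <- mean(vapply(1:4, function(s)
    pmi(giant_component(match_reference(tg$graph, "ba", seed = s)))$phi, 0))
  expect_gt(phi_tsf, phi_ba)
  expect_gt(phi_tsf, phi_er)
})
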
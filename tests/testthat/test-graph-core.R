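# Graph I/O, giant component, density and classical metrics.

test_that("edge lists parse the corpus dialect and are simplified", {
  f <- withr::local_tempfile(fileext = ".edges")
  writeLines(c("% a comment", "# another", "0 1", "1,2", "2 3 0.7", "",
               "1 0"), f)
  expect_message(g <- read_network(f), "dropped 1")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)   # reciprocal "1 0" deduplicated

  writeLines(c("0 1", "oops"), f)
  expect_error(read_network(f), "line 2")

  writeLines(c("3 3", "1 2"), f)
  expect_message(g <- read_network(f), "dropped 1")  # self-loop removed
  expect_equal(igraph::ecount(g), 1)
})

test_that("round-trips preserve the edge set in all three formats", {
  for (fmt in c("edgelist", "mtx", "graphml")) {
    for (seed in 1:5) {
      g <- withr::with_seed(seed, igraph::sample_gnm(30, 60))
      g <- igraph::set_vertex_attr(g, "name", value = as.character(1:30))
      f <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_network(g, f, format = fmt)
      expect_same_graph(read_network(f, format = fmt), g)
    }
  }
  # empty-edge graph survives an edge-list round trip
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  g0 <- igraph::set_vertex_attr(g0, "name", value = as.character(1:5))
  f <- withr::local_tempfile(fileext = ".mtx")
  write_network(g0, f)
  expect_equal(igraph::ecount(read_network(f)), 0)
  expect_equal(igraph::vcount(read_network(f)), 5)
})

test_that("mtx reader enforces pattern/weight semantics", {
  f <- withr::local_tempfile(fileext = ".mtx")
  writeLines(c("%%MatrixMarket matrix coordinate pattern symmetric",
               "4 4 4", "2 1", "3 2", "4 3", "4 1"), f)
  g <- read_network(f)
  expect_same_graph(g, cycle_graph(4))

  writeLines(c("%%MatrixMarket matrix coordinate real symmetric",
               "3 3 2", "2 1 0.5", "3 2 2.0"), f)
  expect_error(read_network(f), "weights")
  expect_message(g <- read_network(f, allow_weights = TRUE), "discarding")
  expect_equal(igraph::ecount(g), 2)
})

test_that("giant_component keeps the largest set and breaks ties low", {
  g <- cycle_graph(5)
  expect_same_graph(giant_component(g), g)

  k3_plus_edge <- igraph::add_edges(
    igraph::disjoint_union(complete_graph(3),
                           igraph::make_empty_graph(2, directed = FALSE)),
    c(4, 5))
  gc <- giant_component(k3_plus_edge)
  expect_equal(igraph::vcount(gc), 3)
  expect_equal(igraph::ecount(gc), 3)

  # two equal components: the one containing vertex 1 wins
  two_edges <- igraph::add_edges(igraph::make_empty_graph(4, directed = FALSE),
                                 c(1, 2, 3, 4))
  gc <- giant_component(two_edges)
  expect_equal(igraph::vcount(gc), 2)
  # exhaustive enumeration oracle: components are {1,2} and {3,4}
  comp <- igraph::components(two_edges)
  expect_true(1 %in% which(comp$membership == comp$membership[1]))
})

test_that("edge density matches the closed form and igraph", {
  expect_equal(edge_density_frac(complete_graph(4)), 1.0)
  expect_equal(edge_density_frac(path_graph(3)), 2 / 3)
  for (seed in 1:10) {
    g <- withr::with_seed(seed, igraph::sample_gnm(20, sample(19:80, 1)))
    m <- igraph::ecount(g)
    expect_identical(edge_density_frac(g), 2 * m / (20 * 19))
    expect_equal(edge_density_frac(g), igraph::edge_density(g))
  }
})

test_that("classical metrics match hand-enumerated values", {
  m5 <- classical_metrics(cycle_graph(5))
  expect_equal(m5$clustering, 0)
  expect_equal(m5$diameter, 2)
  expect_equal(m5$avg_degree, 2)

  m4 <- classical_metrics(complete_graph(4))
  expect_equal(m4$clustering, 1)
  expect_equal(m4$diameter, 1)
  expect_equal(m4$e_glob, 1)
  expect_equal(m4$k_shell, 3)

  # P4: distances 1,1,1,2,2,3 over unordered pairs
  mp <- classical_metrics(path_graph(4))
  expect_equal(mp$l_avg, 10 / 6)
  expect_equal(mp$e_glob, (6 * 1 + 4 * (1 / 2) + 2 * (1 / 3)) / 12)

  expect_error(classical_metrics(igraph::make_empty_graph(3, directed = FALSE) |>
                                   igraph::add_edges(c(1, 2))),
               "giant_component")
})

test_that("efficiency and mean distance respect diameter bounds", {
  for (seed in 1:10) {
    g <- giant_component(withr::with_seed(seed, igraph::sample_gnp(25, 0.12)))
    if (igraph::vcount(g) < 3) next
    met <- classical_metrics(g)
    expect_gte(met$e_glob, 1 / met$diameter)
    expect_lte(met$l_avg, met$diameter)
    expect_gte(met$l_avg, 1)
  }
})
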
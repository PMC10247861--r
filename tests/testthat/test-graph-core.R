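test_that("degree summaries match direct counts", {
  d <- graph_degrees(igraph::make_full_graph(4))
  expect_equal(d$k, rep(3, 4))
  expect_equal(d$k_mean, 3)

  d <- graph_degrees(path_graph(3))
  expect_equal(d$k, c(1, 2, 1))
  expect_equal(d$k_mean, 4 / 3)

  d <- graph_degrees(make_bell("barbell", 8, 3))
  expect_equal(d$k_max, 8)
  expect_equal(d$k_min, 2)

  # handshake lemma on random graphs
  for (i in 1:5) {
    g <- random_connected_graph(8)
    expect_equal(sum(graph_degrees(g)$k), 2 * igraph::ecount(g))
  }
})

test_that("connectivity is detected by traversal", {
  expect_true(is_connected_graph(igraph::make_full_graph(4)))
  two_triangles <- igraph::disjoint_union(igraph::make_ring(3),
                                          igraph::make_ring(3))
  expect_false(is_connected_graph(two_triangles))
  expect_true(is_connected_graph(remove_edge(igraph::make_full_graph(4), 1, 2)))
})

test_that("remove_edge drops exactly one edge and errors on absent edges", {
  p <- remove_edge(igraph::make_ring(3), 1, 2)
  expect_equal(sort(graph_degrees(p)$k), c(1, 1, 2)) # a path

  p4 <- remove_edge(igraph::make_ring(4), 1, 2)
  expect_equal(sort(graph_degrees(p4)$k), c(1, 1, 2, 2))

  k4e <- remove_edge(igraph::make_full_graph(4), 1, 2)
  expect_equal(sort(graph_degrees(k4e)$k), c(2, 2, 3, 3))

  expect_error(remove_edge(igraph::make_ring(4), 1, 3), "not present")
})

test_that("complement behaves as expected and is an involution", {
  expect_equal(igraph::ecount(graph_complement(igraph::make_full_graph(5))), 0)

  c5 <- igraph::make_ring(5)
  expect_identical(canonical_key(graph_complement(c5)), canonical_key(c5))

  two_reg <- igraph::disjoint_union(igraph::make_ring(5), igraph::make_ring(6))
  expect_equal(graph_degrees(graph_complement(two_reg))$k, rep(8, 11))

  set.seed(11)
  for (i in 1:10) {
    g <- igraph::sample_gnp(7, 0.5)
    gc2 <- graph_complement(graph_complement(g))
    expect_equal(adjacency_of(gc2), adjacency_of(g))
  }
})

test_that("cycle-partition complements give the (n-3)-regular input sets", {
  expect_error(regulars_from_cycle_partitions(5), "at least 6")

  for (spec in list(c(11, 6), c(12, 9), c(14, 13))) {
    gs <- regulars_from_cycle_partitions(spec[1])
    expect_length(gs, spec[2])
    for (g in gs) {
      expect_true(is_connected_graph(g))
      expect_equal(graph_degrees(g)$k, rep(spec[1] - 3, spec[1]))
    }
    keys <- vapply(gs, canonical_key, character(1))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("canonical keys classify isomorphism", {
  c5 <- igraph::make_ring(5)
  c5_relab <- igraph::permute(c5, c(3, 5, 1, 2, 4))
  expect_identical(canonical_key(c5), canonical_key(c5_relab))

  c6 <- igraph::make_ring(6)
  two_triangles <- igraph::disjoint_union(igraph::make_ring(3),
                                          igraph::make_ring(3))
  expect_false(canonical_key(c6) == canonical_key(two_triangles))
})

test_that("cospectral keys follow isomorphism and separate distinct spectra", {
  b <- make_bell("barbell", 4, 5)
  b_relab <- igraph::permute(b, sample(igraph::vcount(b)))
  expect_identical(cospectral_key(b), cospectral_key(b_relab))
  expect_identical(cospectral_key(b), cospectral_key(b))

  expect_false(cospectral_key(igraph::make_full_graph(4)) ==
                 cospectral_key(igraph::make_ring(4)))

  # canonical equality implies cospectral equality on random small graphs
  set.seed(42)
  for (i in 1:20) {
    g <- random_connected_graph(sample(4:9, 1))
    h <- igraph::permute(g, sample(igraph::vcount(g)))
    expect_identical(canonical_key(g), canonical_key(h))
    expect_identical(cospectral_key(g), cospectral_key(h))
  }
})

test_that("graph6 encoding matches the reference dialect and round-trips", {
  # reference strings from the standard graph6 specification
  expect_identical(write_read_key(igraph::make_full_graph(5)), "D~{")
  expect_identical(write_read_key(igraph::make_ring(4)), "Cl")
  expect_identical(write_read_key(path_graph(3)), "Bg")
  expect_identical(write_read_key(igraph::make_graph("Petersen")), "IheA@GUAo")

  path <- withr::local_tempfile(fileext = ".g6")
  graphs <- list(igraph::make_full_graph(5), igraph::make_ring(70),
                 random_connected_graph(9))
  write_graph6(graphs, path)
  back <- read_graph6(path)
  expect_length(back, 3)
  for (i in 1:3)
    expect_equal(adjacency_of(back[[i]]), adjacency_of(graphs[[i]]))

  writeLines(character(0), path)
  expect_length(read_graph6(path), 0)

  writeLines(c("D~{", "!!"), path)
  expect_error(read_graph6(path), "line 2")
})

test_that("edge lists round-trip through the 0-based on-disk format", {
  path <- withr::local_tempfile(fileext = ".txt")
  g <- random_connected_graph(8)
  write_edgelist(g, path)
  el <- utils::read.table(path)
  expect_equal(min(el), 0) # 0-based on disk
  back <- read_edgelist(path)
  expect_equal(adjacency_of(back), adjacency_of(g))
})

test_that("the regular-graph enumerator reproduces known counts", {
  expect_length(enumerate_regulars(4, 3), 1) # K4
  expect_length(enumerate_regulars(6, 3), 2)
  expect_length(enumerate_regulars(8, 3), 5)
  expect_length(enumerate_regulars(5, 4), 1) # K5
  for (g in enumerate_regulars(8, 3)) {
    expect_true(is_connected_graph(g))
    expect_equal(graph_degrees(g)$k, rep(3, 8))
  }
})
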
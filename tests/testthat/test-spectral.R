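test_that("Laplacian spectra match closed forms", {
  s <- spectral_summary(igraph::make_full_graph(2))
  expect_equal(s$mu, c(0, 2), tolerance = 1e-12)
  expect_equal(s$lam, c(0, 2), tolerance = 1e-12)

  s4 <- spectral_summary(igraph::make_ring(4))
  expect_equal(s4$mu, c(0, 2, 2, 4), tolerance = 1e-9)

  expect_equal(spectral_summary(igraph::make_full_graph(6))$mu2, 6,
               tolerance = 1e-9)
  expect_equal(spectral_summary(igraph::make_ring(12))$lam2,
               1 - cos(2 * pi / 12), tolerance = 1e-9)

  two <- igraph::disjoint_union(igraph::make_ring(3), igraph::make_ring(4))
  expect_equal(spectral_summary(two)$lam2, 0, tolerance = 1e-9)

  lap <- laplacians(path_graph(3))
  expect_equal(lap$standard, matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3))
  expect_error(laplacians(igraph::make_graph(c(1, 2), n = 3,
                                             directed = FALSE)),
               "isolated")
})

test_that("regular graphs satisfy mu = k * lambda elementwise", {
  for (g in list(igraph::make_graph("Petersen"),
                 regulars_from_cycle_partitions(11)[[3]])) {
    s <- spectral_summary(g)
    k <- graph_degrees(g)$k_mean
    expect_lt(max(abs(s$mu - k * s$lam)), 1e-9)
  }
})

test_that("trace identities hold on random graphs", {
  set.seed(5)
  for (i in 1:20) {
    g <- random_connected_graph(sample(4:12, 1))
    s <- spectral_summary(g)
    expect_equal(sum(s$mu), 2 * igraph::ecount(g), tolerance = 1e-9)
    expect_equal(sum(s$lam), igraph::vcount(g), tolerance = 1e-9)
    expect_true(all(s$lam <= 2 + 1e-9))
  }
})

test_that("interlacing holds for random edge removals", {
  set.seed(13)
  for (i in 1:30) {
    # pick an edge whose removal leaves no isolated vertex (the normalized
    # Laplacian, and hence its interlacing, needs every degree positive);
    # resample the graph when no such edge exists
    repeat {
      g <- random_connected_graph(sample(4:8, 1))
      en <- igraph::ends(g, seq_len(igraph::ecount(g)))
      deg <- igraph::degree(g)
      ok <- which(deg[en[, 1]] >= 2 & deg[en[, 2]] >= 2)
      if (length(ok) > 0) break
    }
    e <- en[ok[sample.int(length(ok), 1)], ]
    chk <- interlacing_check(g, as.numeric(e))
    expect_true(chk$standard_ok)
    expect_true(chk$normalized_ok)
  }
  expect_error(interlacing_check(igraph::make_ring(4), c(1, 3)), "not present")
})

test_that("spectral densities are normalized Gaussian mixtures", {
  wide <- seq(-3, 5, length.out = 8001)
  d1 <- spectral_density(1, sigma = 0.05, grid = wide)
  expect_equal(transamp:::trapz(wide, d1$values), 1, tolerance = 1e-6)

  lam <- spectral_summary(igraph::make_full_graph(5))$lam
  dN <- spectral_density(lam, sigma = 0.02, grid = wide)
  expect_equal(transamp:::trapz(wide, dN$values), 1, tolerance = 1e-6)

  # peak height scales with eigenvalue multiplicity as sigma shrinks
  multi <- spectral_density(c(0, 1, 1, 1, 2), sigma = 1e-3,
                            grid = density_grid())
  single <- spectral_density(c(0, 0.5, 1, 1.5, 2), sigma = 1e-3,
                             grid = density_grid())
  expect_equal(multi$values[which.min(abs(multi$grid - 1))] /
                 single$values[which.min(abs(single$grid - 1))],
               3, tolerance = 1e-3)

  expect_error(spectral_density(1, sigma = 0), "positive")
})

test_that("the spectral distance is a pseudometric numerically", {
  k4 <- igraph::make_full_graph(4)
  c4 <- igraph::make_ring(4)
  expect_equal(spectral_distance(k4, k4), 0, tolerance = 1e-12)
  expect_gt(spectral_distance(k4, c4), 0)
  expect_equal(spectral_distance(k4, c4), spectral_distance(c4, k4))

  set.seed(17)
  for (i in 1:10) {
    gs <- lapply(1:3, function(j) random_connected_graph(6))
    d12 <- spectral_distance(gs[[1]], gs[[2]])
    d13 <- spectral_distance(gs[[1]], gs[[3]])
    d23 <- spectral_distance(gs[[2]], gs[[3]])
    expect_gte(d12, 0)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("ensemble densities average member densities", {
  k4 <- igraph::make_full_graph(4)
  c4 <- igraph::make_ring(4)
  single <- spectral_density(spectral_summary(k4)$lam, sigma = 1 / 12)
  expect_equal(ensemble_density(list(k4))$values, single$values)
  expect_equal(ensemble_density(list(k4, k4))$values, single$values)

  pair <- ensemble_density(list(k4, c4))
  other <- spectral_density(spectral_summary(c4)$lam, sigma = 1 / 12)
  expect_equal(pair$values, (single$values + other$values) / 2)
  expect_error(ensemble_density(list()), "nonempty")
})
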
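test_that("search validates its input and honours the removal bound", {
  expect_error(run_search(path_graph(3)), "regular")
  expect_error(run_search(igraph::make_ring(5)), "regular") # k = 2 < 3

  # K4 exhausts without finding amplifiers (none exist below N = 11)
  res <- run_search(igraph::make_full_graph(4),
                    search_config(mode = "enumerative"))
  expect_length(res$amplifiers, 0)
  expect_lte(max(res$steps$ell), 1 + (3 - 2) * 4 / 2)

  # cubic graph on 12 vertices (Moebius ladder): bound is 1 + (k-2)N/2 = 7
  cub12 <- igraph::graph_from_edgelist(
    rbind(cbind(1:12, c(2:12, 1)), cbind(1:6, 7:12)), directed = FALSE)
  expect_equal(graph_degrees(cub12)$k, rep(3, 12))
  res12 <- run_search(cub12, search_config(filter_size = 30))
  expect_lte(max(res12$steps$ell), 7)
})

test_that("greedy search with unbounded filter equals enumerative search", {
  for (n in c(4, 6, 8)) {
    for (g in enumerate_regulars(n, 3)) {
      enum <- run_search(g, search_config(mode = "enumerative"))
      greedy <- run_search(g, search_config(mode = "greedy",
                                            filter_size = Inf))
      expect_equal(greedy$steps$pool_size, enum$steps$pool_size)
      expect_identical(
        sort(vapply(greedy$amplifiers, `[[`, character(1), "key")),
        sort(vapply(enum$amplifiers, `[[`, character(1), "key")))
    }
  }
})

test_that("every executed edge removal satisfies interlacing (hook on)", {
  g <- enumerate_regulars(6, 3)[[1]]
  expect_no_error(run_search(g, search_config(mode = "enumerative",
                                              check_interlacing = TRUE)))
})

test_that("recorded amplifiers re-verify independently and pools stay bounded", {
  inputs <- regulars_from_cycle_partitions(11)
  res <- run_search(inputs[["8+3"]], search_config(filter_size = 120),
                    input_id = "8+3")
  expect_true(all(res$steps$pool_size <= 120))
  for (a in res$amplifiers) {
    expect_true(is_connected_graph(a$graph))
    expect_gt(effective_population_size(a$graph)$n_eff, 11 + 1e-9)
    expect_equal(nrow(a$lineage), a$removals)
    d <- graph_degrees(a$graph)
    expect_true(d$k_max != d$k_min) # non-regular
  }
})

test_that("campaigns aggregate per-run results coherently", {
  gs <- enumerate_regulars(6, 3)
  camp <- run_campaign(gs, search_config(mode = "enumerative"))
  s <- glance(camp)
  expect_lte(s$inputs_with_amplifier, s$inputs)
  expect_lte(s$nonisomorphic_amplifiers, s$total_amplifiers +
               (s$total_amplifiers == 0))
  expect_error(run_campaign(list(igraph::make_full_graph(4),
                                 igraph::make_full_graph(6))), "same N")
})

test_that("spectral dynamics labels amplifier-bound lineages retrospectively", {
  inputs <- regulars_from_cycle_partitions(11)
  res <- run_search(inputs[["8+3"]],
                    search_config(filter_size = 120, record_dynamics = TRUE),
                    input_id = "8+3")
  expect_gt(length(res$amplifiers), 0)
  dyn <- spectral_dynamics(res)
  expect_s3_class(dyn, "spectral_dynamics")
  expect_gt(nrow(dyn$summary), 0)
  expect_true(all(dyn$summary$distance >= 0))
  expect_true(all(dyn$summary$n_amp >= 1))
  # the amplifier-bound set shrinks to the lineages that reach the amplifier
  expect_true(all(dyn$summary$n_amp <= dyn$summary$n_amp[1] +
                    dyn$summary$n_non[1]))

  # without recording, dynamics are unavailable
  res2 <- run_search(igraph::make_full_graph(4),
                     search_config(mode = "enumerative"))
  expect_error(spectral_dynamics(res2), "record_dynamics")
})

test_that("the mu2 filter variant runs but finds no amplifiers here", {
  inputs <- regulars_from_cycle_partitions(11)
  res <- run_search(inputs[["8+3"]],
                    search_config(filter_size = 60, filter_measure = "mu2"),
                    input_id = "8+3")
  expect_length(res$amplifiers, 0)
})
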
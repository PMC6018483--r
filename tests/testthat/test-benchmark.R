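test_that("scale-free generation has the stated edge count and hub structure", {
  net <- generate_ba_network(3, attach_m = 1, seed = 1)
  expect_equal(sum(net$weights) / 2, 2)       # m=1 tree on 3 vertices

  for (s in 1:3) {
    n <- 60; m <- 2
    net <- generate_ba_network(n, m, seed = s)
    expect_equal(sum(net$weights) / 2, m * (n - m) + choose(m, 2))
    expect_identical(net$weights, t(net$weights))
    g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected")
    expect_true(igraph::is_connected(g))
  }

  # hub property: max degree far exceeds the median over replicates
  degs <- vapply(1:20, function(s) {
    d <- rowSums(generate_ba_network(200, 2, seed = 100 + s)$weights)
    max(d) / stats::median(d)
  }, numeric(1))
  expect_gt(mean(degs), 3)

  expect_error(generate_ba_network(2, 2, seed = 1), "n > attach_m")
})

test_that("planted changes swap neighborhoods of the selected set only", {
  net <- generate_ba_network(80, 2, seed = 5)
  inst <- plant_changes(net, changed_fraction = 0.05, n_networks = 3, seed = 9)
  expect_length(inst$networks, 3)
  expect_length(inst$changed, ceiling(0.05 * 80))
  expect_identical(inst$networks[[1]]$weights, net$weights)

  ch <- match(inst$changed, net$gene_ids)
  for (j in 2:3) {
    B <- inst$networks[[j]]$weights
    # every changed vertex's neighborhood differs
    for (v in ch) expect_false(identical(B[v, ], net$weights[v, ]))
    # unchanged vertices with no changed neighbors keep identical rows
    untouched <- setdiff(seq_len(80), ch)
    clean <- untouched[rowSums(net$weights[untouched, ch, drop = FALSE]) == 0 &
                         rowSums(B[untouched, ch, drop = FALSE]) == 0]
    for (v in clean[seq_len(min(5, length(clean)))]) {
      expect_identical(B[v, ], net$weights[v, ])
    }
  }

  # k = 2 is the smallest plantable set: the pair swaps neighborhoods
  inst2 <- plant_changes(net, changed_fraction = 0.02, n_networks = 2, seed = 3)
  expect_length(inst2$changed, 2)
  expect_error(plant_changes(net, changed_fraction = 0.01, seed = 1),
               "derangement")

  # same seed, same instance
  r1 <- plant_changes(net, 0.05, 2, seed = 44)
  r2 <- plant_changes(net, 0.05, 2, seed = 44)
  expect_identical(r1$changed, r2$changed)
  expect_identical(r1$networks[[2]]$weights, r2$networks[[2]]$weights)
})

test_that("noise injection matches each model's bookkeeping", {
  net <- generate_ba_network(100, 2, seed = 13)
  E <- sum(net$weights != 0) / 2

  for (kind in c("edge_permute", "vertex_delete", "gaussian")) {
    same <- inject_noise(net, kind, level = 0, seed = 1)
    expect_identical(same$weights, net$weights)   # level 0: unchanged
  }

  # edge permutation conserves edge count and moves the right fraction
  ep <- inject_noise(net, "edge_permute", level = 0.3, seed = 7)
  expect_equal(sum(ep$weights != 0) / 2, E)
  moved <- sum(net$weights != 0 & ep$weights == 0) / 2
  expect_equal(moved, round(0.3 * E))

  # vertex deletion zeroes exactly half the rows at level 0.5 (dense
  # network, so no vertex is isolated collaterally)
  dense <- random_network(100, seed = 70, density = 0.5)
  vd <- inject_noise(dense, "vertex_delete", level = 0.5, seed = 7)
  expect_equal(sum(rowSums(vd$weights != 0) == 0), 50)

  # gaussian noise leaves the support intact and perturbs every edge
  gn <- inject_noise(net, "gaussian", level = 2, seed = 7)
  expect_identical(gn$weights != 0, net$weights != 0)
  expect_true(all(gn$weights[net$weights != 0] != net$weights[net$weights != 0]))
  expect_equal(sd(gn$weights[upper.tri(gn$weights) & net$weights != 0] - 1),
               2, tolerance = 0.35)

  expect_error(inject_noise(net, "edge_permute", level = 1.2, seed = 1),
               "<= 1")
})

test_that("the accuracy statistic matches its closed forms", {
  ranked <- tibble::tibble(gene = sprintf("g%02d", 1:10), rank = 1:10)
  expect_equal(accuracy(ranked, c("g09", "g10")), 0.95)
  # all changed at the very end: (N - (|D|-1)/2) / N
  expect_equal(accuracy(ranked, sprintf("g%02d", 8:10)), (10 - 1) / 10)
  expect_error(accuracy(ranked, character(0)), "non-empty")
  expect_error(accuracy(ranked, "g99"), "must appear")

  # monotone: pushing a changed vertex later never decreases accuracy
  a1 <- accuracy(ranked, c("g05", "g10"))
  a2 <- accuracy(ranked, c("g06", "g10"))
  expect_gt(a2, a1)
})

test_that("a noise-free benchmark recovers planted changes almost perfectly", {
  spec <- simulation_spec(n_vertices = 80, noise_kind = "gaussian",
                          noise_levels = 0, mode = c("local", "global"),
                          n_replicates = 4, seed = 19)
  res <- run_benchmark(spec)
  expect_true(all(res$accuracy > 0.95))
  expect_identical(names(res),
                   c("kind", "level", "n_networks", "mode", "replicate",
                     "accuracy"))

  # reproducible bit-for-bit from the spec seed
  res2 <- run_benchmark(spec)
  expect_identical(res, res2)
})
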
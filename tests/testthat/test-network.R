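test_that("thresholded correlation network matches a per-pair oracle", {
  tab <- random_abundance(5, 10, seed = 101)
  X <- tab$values

  # p_threshold = 1 keeps every edge: weights equal the pairwise
  # correlation matrix with zeroed diagonal
  net <- build_correlation_network(tab, method = "pearson", p_threshold = 1)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(net$weights[i, j], unname(oracle_pair_cor(X, i, j)$estimate),
                 tolerance = 1e-12)
  }
  expect_equal(unname(diag(net$weights)), rep(0, 5))

  # at p < 0.05 each edge is either the correlation (p below) or 0
  net05 <- build_correlation_network(tab, method = "pearson",
                                     p_threshold = 0.05)
  for (i in 1:4) for (j in (i + 1):5) {
    ct <- oracle_pair_cor(X, i, j)
    expected <- if (ct$p.value < 0.05) unname(ct$estimate) else 0
    expect_equal(net05$weights[i, j], expected, tolerance = 1e-12)
  }
})

test_that("identical abundance rows give a unit-weight edge", {
  m <- matrix(rnorm(8), 1, 8)
  m <- rbind(m, m, matrix(rnorm(8), 1, 8))
  dimnames(m) <- list(c("a", "b", "c"), paste0("s", 1:8))
  net <- build_correlation_network(abundance_table(m), method = "pearson",
                                   p_threshold = 0.05)
  expect_equal(net$weights["a", "b"], 1)
})

test_that("spearman p-values use the large-sample approximation", {
  tab <- random_abundance(4, 12, seed = 7)
  net <- build_correlation_network(tab, method = "spearman",
                                   p_threshold = 0.3)
  X <- tab$values
  for (i in 1:3) for (j in (i + 1):4) {
    rho <- unname(stats::cor(X[i, ], X[j, ], method = "spearman"))
    tstat <- abs(rho) * sqrt((12 - 2) / (1 - rho^2))
    p <- 2 * stats::pt(tstat, df = 10, lower.tail = FALSE)
    expect_equal(net$weights[i, j], if (p < 0.3) rho else 0,
                 tolerance = 1e-12)
  }
})

test_that("network construction handles missing data, constants and bad input", {
  m <- matrix(rnorm(24), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  m[1, 1:4] <- NA               # leaves only 2 complete pairs vs others
  m[2, ] <- 5                   # constant row
  tab <- abundance_table(m)
  expect_warning(net <- build_correlation_network(tab, "pearson", 1),
                 "Constant")
  expect_equal(unname(net$weights[1, ]), rep(0, 4))  # < 3 complete obs
  expect_equal(unname(net$weights[2, ]), rep(0, 4))  # constant row

  expect_error(build_correlation_network(
    abundance_table(m[, 1:2, drop = FALSE])), "3 samples")
  bad <- data.frame(gene = c("g1", "g2"), s1 = c("1", "x"),
                    s2 = c("2", "3"), s3 = c("1", "2"))
  expect_error(abundance_table(bad), "numeric")
})

test_that("p-threshold sparsification is monotone and permutation-equivariant", {
  tab <- random_abundance(8, 15, seed = 33)
  thresholds <- c(0.01, 0.05, 0.2, 1)
  nets <- lapply(thresholds, function(p) {
    build_correlation_network(tab, "pearson", p)
  })
  for (k in 1:3) {
    lower <- nets[[k]]$weights != 0
    higher <- nets[[k + 1]]$weights != 0
    expect_true(all(higher[lower]))   # raising p never removes an edge
  }
  for (net in nets) {
    expect_identical(net$weights, t(net$weights))
    expect_true(all(diag(net$weights) == 0))
    expect_true(all(abs(net$weights) <= 1))
  }

  perm <- withr::with_seed(1, sample(8))
  tab_p <- abundance_table(tab$values[perm, ], source_name = "perm")
  net_p <- build_correlation_network(tab_p, "pearson", 0.2)
  net_o <- build_correlation_network(tab, "pearson", 0.2)
  expect_equal(unname(net_p$weights),
               unname(net_o$weights[perm, perm]), tolerance = 1e-12)
})

test_that("spearman networks are invariant to monotone row transforms", {
  tab <- random_abundance(6, 12, seed = 55)
  transformed <- tab$values
  transformed[1, ] <- exp(transformed[1, ])
  transformed[2, ] <- transformed[2, ]^3
  transformed[3, ] <- 5 * transformed[3, ] + 2
  tab2 <- abundance_table(transformed)
  n1 <- build_correlation_network(tab, "spearman", 0.5)
  n2 <- build_correlation_network(tab2, "spearman", 0.5)
  expect_equal(n1$weights, n2$weights, tolerance = 1e-12)
})

test_that("edge lists round-trip and orientation does not matter", {
  dir <- withr::local_tempdir()
  one <- file.path(dir, "one.tsv")
  both <- file.path(dir, "both.tsv")
  writeLines(c("a\tb\t0.5", "b\tc\t-0.25"), one)
  writeLines(c("a\tb\t0.5", "b\ta\t0.5", "c\tb\t-0.25"), both)
  n1 <- load_network(one)
  n2 <- load_network(both)
  expect_equal(n1$weights, n2$weights)
  expect_equal(n1$weights["a", "b"], 0.5)
  expect_equal(n1$weights["b", "a"], 0.5)

  # empty list over an explicit universe
  empty <- file.path(dir, "empty.tsv")
  file.create(empty)
  n0 <- load_network(empty, gene_universe = c("x", "y", "z"))
  expect_equal(unname(n0$weights), matrix(0, 3, 3))

  # self-loops warn, contradictions reject
  loop <- file.path(dir, "loop.tsv")
  writeLines(c("a\ta\t1", "a\tb\t0.1"), loop)
  expect_warning(nl <- load_network(loop), "self-loop")
  expect_equal(nl$weights["a", "b"], 0.1)
  contra <- file.path(dir, "contra.tsv")
  writeLines(c("a\tb\t0.5", "b\ta\t0.7"), contra)
  expect_error(load_network(contra), "Contradictory")

  # write_network round-trip with header
  net <- random_network(5, seed = 9)
  out <- file.path(dir, "net.tsv")
  write_network(net, out)
  back <- load_network(out, gene_universe = net$gene_ids)
  expect_equal(back$weights, net$weights, tolerance = 1e-12)
})

test_that("gene-universe alignment intersects and zero-pads correctly", {
  Wa <- matrix(c(0, .5, .2, .5, 0, 0, .2, 0, 0), 3, 3)
  Wb <- matrix(c(0, .1, 0, .1, 0, .3, 0, .3, 0), 3, 3)
  na <- make_net(Wa, c("a", "b", "c"))
  nb <- make_net(Wb, c("b", "c", "d"))

  ints <- align_gene_universe(list(na, nb), "intersection")
  expect_identical(ints[[1]]$gene_ids, c("b", "c"))
  expect_equal(ints[[1]]$weights["b", "c"], 0)
  expect_equal(ints[[2]]$weights["b", "c"], 0.1)

  uni <- align_gene_universe(list(na, nb), "union")
  expect_identical(uni[[1]]$gene_ids, c("a", "b", "c", "d"))
  expect_equal(sum(abs(uni[[1]]$weights[, "d"])), 0)  # d absent from first
  expect_equal(uni[[2]]$weights["b", "c"], 0.1)

  same <- align_gene_universe(list(na, na), "intersection")
  expect_equal(same[[1]]$weights, na$weights)

  nc <- make_net(matrix(0, 2, 2), c("x", "y"))
  expect_error(align_gene_universe(list(na, nc), "intersection"),
               "empty intersection")
})
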
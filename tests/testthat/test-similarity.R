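test_that("cosine follows its closed form and zero-vector contract", {
  expect_equal(cosine(c(3, 4), c(3, 4)), 1)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_equal(cosine(c(0, 0), c(1, 2)), 0)    # isolated gene contract
  expect_error(cosine(1:3, 1:2), "equal length")
})

test_that("local similarity equals row-wise cosine of adjacency rows", {
  W <- matrix(c(0, .5, -.2, 0,
                .5, 0, .3, 0,
                -.2, .3, 0, 0,
                0, 0, 0, 0), 4, 4)
  A <- make_net(W)
  Bw <- matrix(c(0, .1, 0, .4,
                 .1, 0, .6, 0,
                 0, .6, 0, 0,
                 .4, 0, 0, 0), 4, 4)
  B <- make_net(Bw)
  ls <- local_similarity(A, B)
  expect_equal(ls$score, oracle_row_cosine(W, Bw), tolerance = 1e-12)

  # identity: a network against itself scores 1 on non-isolated vertices
  self <- local_similarity(A, A)
  expect_equal(self$score[1:3], rep(1, 3))
  expect_equal(self$score[4], 0)               # isolated row scores 0

  expect_error(local_similarity(A, make_net(Bw, letters[1:4])),
               "identical ordered gene index")
})

test_that("transition matrix |w|-normalizes rows and absorbs isolated vertices", {
  tri <- make_net(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  Wt <- transition_matrix(tri)
  expect_equal(unname(Wt$probs),
               matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, 3))

  mixed <- make_net(matrix(c(0, .6, -.3, .6, 0, 0, -.3, 0, 0), 3, 3))
  Wm <- transition_matrix(mixed)
  expect_equal(unname(Wm$probs[1, ]), c(0, 2 / 3, 1 / 3))

  iso <- make_net(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3))
  Wi <- transition_matrix(iso)
  expect_equal(unname(Wi$probs[3, ]), c(0, 0, 1))  # absorbing
  expect_equal(unname(rowSums(Wi$probs)), rep(1, 3))

  clip <- transition_matrix(mixed, negative = "clip")
  expect_equal(unname(clip$probs[1, ]), c(0, 1, 0))
})

test_that("stationary distributions satisfy the closed form", {
  # beta = 1 reduces to the seed indicator exactly
  net <- random_network(6, seed = 3, signed = FALSE)
  W <- transition_matrix(net)
  s <- stationary_distribution(W, 2, rwr_config(1))
  expect_identical(unname(s), c(0, 1, 0, 0, 0, 0))

  # 2-vertex closed form: beta = 0.5 gives (2/3, 1/3)
  two <- make_net(matrix(c(0, 1, 1, 0), 2, 2))
  s2 <- stationary_distribution(transition_matrix(two), 1, rwr_config(0.5))
  expect_equal(unname(s2), c(2 / 3, 1 / 3), tolerance = 1e-12)

  # any seed: nonnegative, sums to 1 within 1e-10; matches the
  # fixed-point oracle; profile rows agree with single-seed solves
  prof <- stationary_profile(net, rwr_config(0.4))
  for (i in seq_len(6)) {
    si <- stationary_distribution(W, i, rwr_config(0.4))
    expect_true(all(si >= 0))
    expect_equal(sum(si), 1, tolerance = 1e-10)
    expect_equal(unname(si), oracle_rwr(W$probs, i, 0.4), tolerance = 1e-9)
    expect_equal(unname(prof$dist[i, ]), unname(si), tolerance = 1e-10)
  }
})

test_that("per-vertex restart probabilities are honored", {
  net <- random_network(5, seed = 8, signed = FALSE)
  W <- transition_matrix(net)
  betas <- c(0.2, 0.4, 0.6, 0.8, 1)
  prof <- stationary_profile(net, rwr_config(betas))
  for (i in seq_len(5)) {
    expect_equal(unname(prof$dist[i, ]),
                 oracle_rwr(W$probs, i, betas[i]), tolerance = 1e-9)
  }
})

test_that("global similarity matches the explicit-inverse oracle", {
  a <- random_network(7, seed = 21)
  b <- random_network(7, seed = 22)
  gs <- global_similarity(a, b, rwr_config(0.4))
  Sa <- oracle_rwr_profile(transition_matrix(a)$probs, 0.4)
  Sb <- oracle_rwr_profile(transition_matrix(b)$probs, 0.4)
  expect_equal(gs$score, oracle_row_cosine(Sa, Sb), tolerance = 1e-8)
  expect_true(all(gs$score >= 0 & gs$score <= 1 + 1e-12))

  # identical networks and beta -> 1 both give all-ones
  expect_equal(global_similarity(a, a, rwr_config(0.4))$score, rep(1, 7))
  expect_equal(global_similarity(a, b, rwr_config(1))$score, rep(1, 7))
})

test_that("similarity is symmetric, permutation-equivariant and scale-aware", {
  a <- random_network(8, seed = 31)
  b <- random_network(8, seed = 32)
  expect_equal(local_similarity(a, b)$score, local_similarity(b, a)$score)
  expect_equal(global_similarity(a, b)$score, global_similarity(b, a)$score)

  perm <- withr::with_seed(2, sample(8))
  ap <- make_net(a$weights[perm, perm], a$gene_ids[perm])
  bp <- make_net(b$weights[perm, perm], b$gene_ids[perm])
  expect_equal(local_similarity(ap, bp)$score,
               local_similarity(a, b)$score[perm], tolerance = 1e-12)
  expect_equal(global_similarity(ap, bp)$score,
               global_similarity(a, b)$score[perm], tolerance = 1e-10)

  # cosine scale-invariance of local scores on nonnegative weights
  an <- make_net(abs(a$weights))
  bn <- make_net(abs(b$weights))
  bs <- make_net(3.7 * abs(b$weights))
  expect_equal(local_similarity(an, bs)$score,
               local_similarity(an, bn)$score, tolerance = 1e-12)
})

test_that("global scores vary continuously in beta toward 1", {
  a <- random_network(6, seed = 41)
  b <- random_network(6, seed = 42)
  betas <- c(0.4, 0.7, 0.9, 0.99, 0.999)
  scores <- vapply(betas, function(bb) {
    mean(global_similarity(a, b, rwr_config(bb))$score)
  }, numeric(1))
  expect_true(all(diff(scores) > -1e-9))   # approaches the all-ones limit
  expect_gt(scores[5], 0.99)
})
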
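# Independent oracles and small fixture builders shared across tests.
# Every oracle is a second, deliberately naive route to the same
# quantity; none calls into the code path it checks.

# direct elementwise cosine (loop-free but formula-literal)
oracle_cosine <- function(x, y) {
  sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
}

# per-row cosine by explicit looping
oracle_row_cosine <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    x <- A[i, ]; y <- B[i, ]
    if (all(x == 0) || all(y == 0)) return(0)
    oracle_cosine(x, y)
  }, numeric(1))
}

# per-pair correlation + p-value via stats::cor.test (the reference
# route for a single pair of abundance rows)
oracle_pair_cor <- function(X, i, j, method = "pearson") {
  ok <- complete.cases(X[i, ], X[j, ])
  suppressWarnings(stats::cor.test(X[i, ok], X[j, ok], method = method,
                                   exact = FALSE))
}

# restart-walk stationary distribution by fixed-point iteration
# s = beta * e + (1 - beta) * s W  (row-vector convention)
oracle_rwr <- function(W, i, beta, tol = 1e-13, max_iter = 100000) {
  n <- nrow(W)
  e <- numeric(n); e[i] <- 1
  s <- e
  for (k in seq_len(max_iter)) {
    s_new <- beta * e + (1 - beta) * as.numeric(s %*% W)
    if (max(abs(s_new - s)) < tol) return(s_new)
    s <- s_new
  }
  stop("oracle_rwr failed to converge")
}

oracle_rwr_profile <- function(W, beta) {
  t(vapply(seq_len(nrow(W)), function(i) oracle_rwr(W, i, beta),
           numeric(nrow(W))))
}

# Efron BCa on a fixed resample-index stream, written independently:
# explicit loops, sort-based order-statistic quantiles.
oracle_bca <- function(x, y, idx, alpha) {
  n <- length(x)
  B <- nrow(idx)
  theta_hat <- oracle_cosine(x, y)
  theta_b <- numeric(B)
  for (b in seq_len(B)) {
    xs <- x[idx[b, ]]; ys <- y[idx[b, ]]
    theta_b[b] <- if (all(xs == 0) || all(ys == 0)) 0 else oracle_cosine(xs, ys)
  }
  if (max(theta_b) == min(theta_b)) return(c(theta_b[1], theta_b[1]))
  prop <- sum(theta_b < theta_hat) / B
  prop <- max(min(prop, 1 - 1 / (2 * B)), 1 / (2 * B))
  z0 <- qnorm(prop)
  theta_jack <- numeric(n)
  for (i in seq_len(n)) {
    xs <- x[-i]; ys <- y[-i]
    theta_jack[i] <- if (all(xs == 0) || all(ys == 0)) 0 else oracle_cosine(xs, ys)
  }
  d <- mean(theta_jack) - theta_jack
  a <- if (sum(d^2) == 0) 0 else sum(d^3) / (6 * sum(d^2)^1.5)
  adj <- function(z_alpha) {
    pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))
  }
  sorted <- sort(theta_b)
  at <- function(p) {
    k <- ceiling(p * B)
    sorted[max(1, min(k, B))]
  }
  c(at(adj(qnorm(alpha / 2))), at(adj(qnorm(1 - alpha / 2))))
}

# build a correlation_network from a dense symmetric matrix
make_net <- function(W, ids = NULL) {
  ids <- ids %||% paste0("g", seq_len(nrow(W)))
  dimnames(W) <- list(ids, ids)
  correlation_network(W)
}

# random sparse symmetric weighted network
random_network <- function(n, seed, density = 0.3, signed = TRUE) {
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W))
    on_idx <- sample(ut, round(density * length(ut)))
    w <- runif(length(on_idx), 0.1, 1)
    if (signed) w <- w * sample(c(-1, 1), length(w), replace = TRUE)
    W[on_idx] <- w
    W <- W + t(W)
    make_net(W)
  })
}

# small two-phenotype abundance matrix with named dims
random_abundance <- function(n_genes, n_samples, seed, source_name = "src") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    abundance_table(m, source_name = source_name)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a small two-source/two-phenotype abundance fixture as TSVs
write_fixture_tsvs <- function(dir, seed = 77) {
  sim <- simulate_abundance_pair(n_genes = 20, samples_per_phenotype = 8,
                                 seed = seed)
  paths <- list(a = file.path(dir, "a.tsv"), b = file.path(dir, "b.tsv"),
                meta = file.path(dir, "meta.tsv"))
  for (k in c("a", "b")) {
    tab <- sim$tables[[paste0("source_", k)]]
    df <- tibble::as_tibble(tab$values, rownames = "gene")
    readr::write_tsv(df, paths[[k]], progress = FALSE)
  }
  readr::write_tsv(tibble::tibble(sample_id = sim$tables[[1]]$sample_ids,
                                  phenotype = sim$tables[[1]]$phenotype),
                   paths$meta, progress = FALSE)
  paths
}
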
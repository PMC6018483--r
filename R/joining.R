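#' Join pairwise similarity score vectors into final per-gene scores
#'
#' With l data sources there are `choose(l, 2)` pairwise score vectors;
#' the joining function f combines them elementwise into one score per
#' gene. With exactly two sources f is the identity.
#'
#' @param pair_scores List of pairwise score tibbles (columns `gene`,
#'   `score`) over one shared gene index, as returned by
#'   [local_similarity()] or [global_similarity()].
#' @param method One of `"mean"` (default), `"max"`, `"min"`,
#'   `"geometric_mean"`, `"identity"`. `"identity"` is only valid for a
#'   single pair; `"geometric_mean"` rejects negative scores.
#' @return A tibble with columns `gene` and `score`.
#' @export
join_scores <- function(pair_scores,
                        method = c("mean", "max", "min",
                                   "geometric_mean", "identity")) {
  method <- match.arg(method)
  if (!is.list(pair_scores) || length(pair_scores) == 0) {
    abort("`pair_scores` must be a non-empty list of score tibbles.")
  }
  if (inherits(pair_scores, "data.frame")) pair_scores <- list(pair_scores)
  genes <- pair_scores[[1]]$gene
  walk(pair_scores, function(p) {
    if (!identical(p$gene, genes)) {
      abort("All pairwise score vectors must share one ordered gene index.")
    }
  })
  M <- do.call(cbind, lapply(pair_scores, function(p) p$score))
  if (method == "identity") {
    if (ncol(M) != 1) {
      abort("`identity` joining is only permitted for exactly one pair of sources.")
    }
    score <- M[, 1]
  } else if (method == "geometric_mean") {
    if (any(M < 0)) {
      abort(paste("Geometric-mean joining is undefined for negative scores",
                  "(local similarity can be negative); use mean/min/max."))
    }
    score <- exp(rowMeans(log(pmax(M, .Machine$double.xmin))))
    score[rowSums(M == 0) > 0] <- 0
  } else {
    score <- switch(method,
                    mean = rowMeans(M),
                    max = apply(M, 1, max),
                    min = apply(M, 1, min))
  }
  tibble(gene = genes, score = unname(score))
}

#' Bootstrap configuration for BCa confidence intervals
#'
#' @param n_resamples Number of bootstrap replicates (default 1000).
#' @param alpha Two-sided miscoverage; the interval level is
#'   `1 - alpha` (default 0.05, i.e. 95%).
#' @param resample_size Size of each resample; defaults to the full
#'   vector length (the standard bootstrap). Smaller values give
#'   m-out-of-n subsampling.
#' @param seed Integer seed; required, so every interval is
#'   deterministic and no hidden RNG state is consumed.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_resamples = 1000, alpha = 0.05,
                             resample_size = NULL, seed) {
  if (missing(seed)) abort("`seed` is required for bootstrap resampling.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (n_resamples < 1) abort("`n_resamples` must be positive.")
  structure(list(n_resamples = as.integer(n_resamples), alpha = alpha,
                 resample_size = resample_size, seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' BCa bootstrap confidence interval for a cosine similarity
#'
#' Resamples coordinate *pairs* (index pairing between `x` and `y` is
#' always maintained) and recomputes the cosine per replicate; the
#' interval is Efron's bias-corrected and accelerated (BCa) interval:
#' bias correction from the fraction of replicate statistics below the
#' point estimate, acceleration from the skewness of jackknife
#' leave-one-out statistics. A replicate whose resampled vectors are
#' all-zero contributes statistic 0 (the zero-vector cosine contract).
#'
#' @param x,y Numeric vectors of equal length (>= 3): the two vectors
#'   whose cosine is the statistic (neighbor-weight rows for local
#'   similarity, stationary distributions for global).
#' @param cfg A [bootstrap_config()].
#' @return A one-row tibble with columns `ci_low`, `ci_high`,
#'   `ci_width`.
#' @export
bca_ci <- function(x, y, cfg) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 coordinate pairs.")
  m <- cfg$resample_size %||% length(x)
  if (m > length(x)) abort("`resample_size` cannot exceed the vector length.")
  idx <- with_seed(cfg$seed, {
    matrix(sample.int(length(x), cfg$n_resamples * m, replace = TRUE),
           nrow = cfg$n_resamples)
  })
  ci <- bca_from_indices(x, y, idx, cfg$alpha)
  tibble(ci_low = ci[1], ci_high = ci[2], ci_width = ci[2] - ci[1])
}

# Core BCa computation given a fixed resample-index matrix (rows are
# replicates). Exposed internally so oracle tests can share the stream.
bca_from_indices <- function(x, y, idx, alpha) {
  theta_hat <- cosine(x, y)
  B <- nrow(idx)
  xb <- matrix(x[idx], nrow = B)
  yb <- matrix(y[idx], nrow = B)
  theta_b <- row_cosine(xb, yb)
  if (max(theta_b) - min(theta_b) <= 0) {
    return(c(theta_b[1], theta_b[1]))
  }
  prop <- mean(theta_b < theta_hat)
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- qnorm(prop)
  # O(n) leave-one-out cosines for the acceleration constant
  sxy <- sum(x * y); sxx <- sum(x^2); syy <- sum(y^2)
  num <- sxy - x * y
  den <- sqrt(pmax(sxx - x^2, 0) * pmax(syy - y^2, 0))
  theta_jack <- ifelse(den > 0, num / den, 0)
  d <- mean(theta_jack) - theta_jack
  denom <- sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  zl <- qnorm(alpha / 2)
  zu <- qnorm(1 - alpha / 2)
  a1 <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  st <- sort(theta_b)
  pick <- function(p) st[min(max(ceiling(p * B), 1), B)]
  c(pick(a1), pick(a2))
}

# Attach per-gene BCa intervals given the two matrices whose rows fed
# the final cosine (adjacency rows for local mode, stationary
# distributions for global). One seeded stream drives all genes.
attach_ci_rows <- function(result, XA, XB, cfg) {
  n <- ncol(XA)
  m <- cfg$resample_size %||% n
  G <- nrow(XA)
  ci <- matrix(NA_real_, G, 2)
  with_seed(cfg$seed, {
    for (g in seq_len(G)) {
      idx <- matrix(sample.int(n, cfg$n_resamples * m, replace = TRUE),
                    nrow = cfg$n_resamples)
      ci[g, ] <- bca_from_indices(XA[g, ], XB[g, ], idx, cfg$alpha)
    }
  })
  result$ci_low <- ci[, 1]
  result$ci_high <- ci[, 2]
  result$ci_width <- ci[, 2] - ci[, 1]
  result
}

#' Rank genes by similarity score
#'
#' Orders genes by descending score (rank 1 = most conserved). Ties are
#' broken by ascending confidence-interval width (narrower = more
#' confident ranks first), then lexicographic gene identifier.
#'
#' @param result A tibble with columns `gene`, `score`, and optionally
#'   `ci_width` (e.g. from [differential_integrate()] or
#'   [join_scores()]).
#' @return The input rows reordered, with a `rank` column appended.
#' @export
rank_genes <- function(result) {
  stopifnot(all(c("gene", "score") %in% names(result)))
  w <- if ("ci_width" %in% names(result)) {
    ifelse(is.na(result$ci_width), 0, result$ci_width)
  } else {
    rep(0, nrow(result))
  }
  out <- result[order(-result$score, w, result$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  as_tibble(out)
}

#' Aggregate ranked gene lists by rank product
#'
#' The rank product of a gene is the geometric mean of its ranks across
#' lists; genes consistently near the top of every list get small rank
#' products. Significance comes from a permutation null that shuffles
#' the ranks independently within each list, with the +1 pseudocount
#' estimator `p = (#{permutation RP <= observed} + 1) / (n_perm + 1)`.
#'
#' @param lists List of ranked tibbles over one common gene universe,
#'   each with columns `gene` and `rank` (or `score`, in which case
#'   [rank_genes()] is applied first).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @return A tibble with columns `gene`, `rp`, `p_value`, `rank`,
#'   ordered by ascending rank product.
#' @export
rank_product <- function(lists, n_perm = 1000, seed) {
  if (missing(seed)) abort("`seed` is required for the permutation null.")
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  stopifnot(is.list(lists), length(lists) >= 1)
  lists <- lapply(lists, function(l) {
    if (!"rank" %in% names(l)) l <- rank_genes(l)
    l
  })
  genes <- sort(lists[[1]]$gene)
  walk(lists, function(l) {
    if (!identical(sort(l$gene), genes)) {
      abort("All lists must cover the same gene universe.")
    }
  })
  R <- vapply(lists, function(l) l$rank[match(genes, l$gene)],
              numeric(length(genes)))
  R <- matrix(R, nrow = length(genes))
  log_rp_obs <- rowMeans(log(R))
  exceed <- integer(length(genes))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      Rp <- apply(R, 2, sample)
      exceed <- exceed + (rowMeans(log(Rp)) <= log_rp_obs + 1e-12)
    }
  })
  out <- tibble(
    gene = genes,
    rp = exp(log_rp_obs),
    p_value = (exceed + 1) / (n_perm + 1)
  ) |> arrange(.data$rp, .data$gene)
  out$rank <- seq_len(nrow(out))
  out
}
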
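#' Cosine similarity of two vectors
#'
#' `sum(x * y) / (||x|| * ||y||)`. The cosine is undefined when either
#' vector is all-zero; by contract it is then 0: an isolated or
#' unmeasured gene is maximally non-conserved.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
#' @examples
#' cosine(c(1, 1), c(1, 0))  # 1 / sqrt(2)
cosine <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 1) abort("Vectors must have length >= 1.")
  den <- sqrt(sum(x^2) * sum(y^2))
  if (den == 0) return(0)
  sum(x * y) / den
}

# Row-wise cosine of two conformable matrices; all-zero rows give 0.
row_cosine <- function(X, Y) {
  num <- rowSums(X * Y)
  den <- sqrt(rowSums(X^2) * rowSums(Y^2))
  ifelse(den > 0, num / den, 0)
}

check_shared_universe <- function(a, b) {
  if (!identical(a$gene_ids, b$gene_ids)) {
    abort("Networks must share an identical ordered gene index; see align_gene_universe().")
  }
}

pair_scores <- function(gene_ids, scores, mode) {
  out <- tibble(gene = gene_ids, score = unname(scores))
  attr(out, "mode") <- mode
  class(out) <- c("pair_scores", class(out))
  out
}

#' Local (one-hop) vertex similarity between two networks
#'
#' The local similarity of gene i is the cosine between its edge-weight
#' rows in the two adjacency matrices: the network topology one hop
#' away from the vertex. A vertex isolated in either network scores 0.
#'
#' @param a,b [correlation_network()]s over an identical ordered gene
#'   index (use [align_gene_universe()] first).
#' @return A tibble with columns `gene` and `score` (in \[-1, 1\]),
#'   with attribute `mode = "local"`.
#' @export
local_similarity <- function(a, b) {
  check_shared_universe(a, b)
  pair_scores(a$gene_ids, row_cosine(a$weights, b$weights), "local")
}

#' Row-stochastic transition matrix of a network
#'
#' The transition probability from i to j is the absolute edge weight
#' normalized by the total absolute weight at i (association strength
#' drives transition mass regardless of sign; set
#' `negative = "clip"` to discard negative edges instead). Isolated
#' vertices are made absorbing (`probs[i, i] = 1`) so the restart walk
#' stays well-defined.
#'
#' @param net A [correlation_network()].
#' @param negative `"absolute"` (default) or `"clip"`.
#' @return An object of class `transition_matrix` with fields
#'   `gene_ids` and `probs` (rows sum to 1).
#' @export
transition_matrix <- function(net, negative = c("absolute", "clip")) {
  stopifnot(inherits(net, "correlation_network"))
  negative <- match.arg(negative)
  W <- if (negative == "absolute") abs(net$weights) else pmax(net$weights, 0)
  rs <- rowSums(W)
  isolated <- rs == 0
  W[!isolated, ] <- W[!isolated, , drop = FALSE] / rs[!isolated]
  if (any(isolated)) {
    W[isolated, ] <- 0
    W[cbind(which(isolated), which(isolated))] <- 1
  }
  structure(list(gene_ids = net$gene_ids, probs = W),
            class = "transition_matrix")
}

#' Random-walk-with-restart configuration
#'
#' @param restart_prob Restart probability beta in (0, 1\]: the chance
#'   per step that the walk teleports back to its seed vertex; smaller
#'   values diffuse further. Default 0.4 follows the network-propagation
#'   convention. May be a per-vertex vector.
#' @param solver_tolerance Numerical tolerance for the stationary
#'   distribution (row sums are checked against 1 at this tolerance).
#' @return An object of class `rwr_config`.
#' @export
rwr_config <- function(restart_prob = 0.4, solver_tolerance = 1e-10) {
  if (any(restart_prob <= 0 | restart_prob > 1)) {
    abort("`restart_prob` must lie in (0, 1].")
  }
  structure(list(restart_prob = restart_prob,
                 solver_tolerance = solver_tolerance),
            class = "rwr_config")
}

#' Stationary distributions of the restart walk at every seed
#'
#' For seed vertex i the stationary visit distribution is
#' `s[i, ] = beta_i * e(i) %*% solve(I - (1 - beta_i) * W)`,
#' the closed form of a random walk that steps along `W` with
#' probability `1 - beta_i` and restarts at i with probability
#' `beta_i`. Computed by one linear solve per distinct beta (not an
#' explicit inverse per seed); each row is nonnegative and sums to 1.
#'
#' @param x A [correlation_network()] or [transition_matrix()].
#' @param cfg An [rwr_config()].
#' @return An object of class `stationary_profile` with fields
#'   `gene_ids` and `dist` (row i is the distribution seeded at i).
#' @export
stationary_profile <- function(x, cfg = rwr_config()) {
  W <- if (inherits(x, "correlation_network")) transition_matrix(x) else x
  stopifnot(inherits(W, "transition_matrix"))
  n <- length(W$gene_ids)
  beta <- rep_len(cfg$restart_prob, n)
  S <- matrix(NA_real_, n, n, dimnames = list(W$gene_ids, W$gene_ids))
  for (b in unique(beta)) {
    rows <- which(beta == b)
    if (b == 1) {
      Sb <- diag(n)
    } else {
      Sb <- b * solve(diag(n) - (1 - b) * W$probs)
    }
    S[rows, ] <- Sb[rows, , drop = FALSE]
  }
  bad <- abs(rowSums(S) - 1) > max(cfg$solver_tolerance, 1e-8)
  if (any(bad)) {
    abort("Stationary distribution rows failed to normalize; singular system?")
  }
  S[S < 0 & S > -cfg$solver_tolerance] <- 0
  structure(list(gene_ids = W$gene_ids, dist = S),
            class = "stationary_profile")
}

#' Stationary distribution of the restart walk seeded at one vertex
#'
#' @param W A [transition_matrix()].
#' @param i Seed vertex: gene identifier or index.
#' @param cfg An [rwr_config()] (scalar restart probability applied at
#'   the seed).
#' @return Numeric vector over the gene index; nonnegative, sums to 1.
#' @export
stationary_distribution <- function(W, i, cfg = rwr_config()) {
  stopifnot(inherits(W, "transition_matrix"))
  n <- length(W$gene_ids)
  if (is.character(i)) i <- match(i, W$gene_ids)
  if (is.na(i) || i < 1 || i > n) abort("Seed vertex not in the gene universe.")
  beta <- rep_len(cfg$restart_prob, n)[i]
  e <- numeric(n)
  e[i] <- 1
  if (beta == 1) return(setNames(e, W$gene_ids))
  # s = beta * e^T (I - (1-beta) W)^{-1}  =>  solve the transposed system
  s <- beta * solve(t(diag(n) - (1 - beta) * W$probs), e)
  s[s < 0 & s > -cfg$solver_tolerance] <- 0
  setNames(as.numeric(s), W$gene_ids)
}

#' Global (random-walk) vertex similarity between two networks
#'
#' The global similarity of gene i is the cosine between the two
#' stationary restart-walk distributions seeded at i, one per network:
#' a multi-hop view of the vertex neighborhood. Scores lie in \[0, 1\]
#' (cosines of nonnegative vectors).
#'
#' @inheritParams local_similarity
#' @param cfg An [rwr_config()].
#' @return A tibble with columns `gene` and `score`, attribute
#'   `mode = "global"`.
#' @export
global_similarity <- function(a, b, cfg = rwr_config()) {
  check_shared_universe(a, b)
  sa <- stationary_profile(a, cfg)
  sb <- stationary_profile(b, cfg)
  pair_scores(a$gene_ids, row_cosine(sa$dist, sb$dist), "global")
}
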
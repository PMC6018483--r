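#' Generate a scale-free benchmark network
#'
#' Barabási–Albert preferential attachment: starting from a single
#' vertex, each new vertex attaches `attach_m` edges to existing
#' vertices with probability proportional to degree (fewer while fewer
#' than `attach_m` vertices exist), yielding a connected network with
#' hubs and exactly `attach_m * (n - attach_m) + choose(attach_m, 2)`
#' edges. All edge weights are 1; this is the noise-free stand-in for
#' an interactome measured by one assay.
#'
#' @param n Number of vertices (`n > attach_m`).
#' @param attach_m Edges attached per new vertex (>= 1).
#' @param seed Integer seed.
#' @return A [correlation_network()] with unit weights.
#' @export
generate_ba_network <- function(n, attach_m = 2, seed) {
  if (attach_m < 1 || n <= attach_m) {
    abort("Need n > attach_m >= 1.")
  }
  g <- with_seed(seed, igraph::sample_pa(n, m = attach_m, directed = FALSE))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  A[A > 1] <- 1
  ids <- sprintf("g%0*d", nchar(n), seq_len(n))
  dimnames(A) <- list(ids, ids)
  correlation_network(A, source_name = "ba_network")
}

#' Plant known vertex changes across simulated data sources
#'
#' Selects a fraction of vertices uniformly and, for every additional
#' data source, applies an independent cyclic derangement of their
#' identities (each selected vertex takes over another selected
#' vertex's neighborhood). The selected set is the planted ground
#' truth: the "difference" between data sources that the integration
#' should push to the bottom of the ranked list.
#'
#' @param net Base [correlation_network()].
#' @param changed_fraction Fraction of vertices to change (default
#'   0.05); `ceiling(changed_fraction * n)` must be >= 2 (no
#'   derangement of fewer vertices exists).
#' @param n_networks Total number of data sources (2 or 3): the base
#'   network plus `n_networks - 1` derived networks.
#' @param seed Integer seed.
#' @return An object of class `planted_instance`: fields `networks`
#'   (list of length `n_networks`, first element the base), `changed`
#'   (gene identifiers of the planted set), `changed_fraction`.
#' @export
plant_changes <- function(net, changed_fraction = 0.05, n_networks = 2, seed) {
  stopifnot(inherits(net, "correlation_network"))
  if (changed_fraction <= 0 || changed_fraction >= 1) {
    abort("`changed_fraction` must lie in (0, 1).")
  }
  if (!n_networks %in% c(2, 3)) abort("`n_networks` must be 2 or 3.")
  n <- length(net$gene_ids)
  k <- ceiling(changed_fraction * n)
  if (k < 2) abort("Fewer than 2 changed vertices: no derangement exists.")
  with_seed(seed, {
    for (attempt in 1:50) {
      changed <- sort(sample(n, k))
      nets <- vector("list", n_networks)
      nets[[1]] <- net
      ok <- TRUE
      for (j in seq_len(n_networks - 1)) {
        ord <- sample(changed)
        perm <- seq_len(n)
        perm[ord] <- c(ord[-1], ord[1])   # cyclic shift: a derangement
        B <- net$weights[perm, perm]
        dimnames(B) <- list(net$gene_ids, net$gene_ids)
        if (any(vapply(changed, function(v) {
          identical(B[v, ], net$weights[v, ])
        }, logical(1)))) {
          ok <- FALSE
          break
        }
        nets[[j + 1]] <- correlation_network(B, source_name = sprintf("derived_%d", j))
      }
      if (ok) break
    }
    if (!ok) abort("Could not plant changes with differing neighborhoods.")
    structure(list(networks = nets,
                   changed = net$gene_ids[changed],
                   changed_fraction = changed_fraction),
              class = "planted_instance")
  })
}

#' Inject noise into a network
#'
#' Three noise models emulating unreliable high-throughput data:
#' * `edge_permute` — misplaced edges: a uniformly chosen fraction of
#'   existing edges is rewired to uniformly chosen currently-empty
#'   vertex pairs (weights carried along).
#' * `vertex_delete` — missing measurements: a uniformly chosen
#'   fraction of vertices has its rows/columns zeroed; the vertex
#'   stays in the universe, emulating a gene unmeasured by one assay.
#' * `gaussian` — noisy edge values: independent `N(0, level^2)` draws
#'   added to every existing edge weight (`level` is the standard
#'   deviation sigma).
#'
#' @param net A [correlation_network()].
#' @param kind `"edge_permute"`, `"vertex_delete"`, or `"gaussian"`.
#' @param level Fraction of edges/vertices for the first two kinds
#'   (the benchmark sweeps 0–0.5); sigma >= 0 for `gaussian` (swept
#'   0–6).
#' @param seed Integer seed.
#' @return The perturbed [correlation_network()].
#' @export
inject_noise <- function(net, kind = c("edge_permute", "vertex_delete",
                                       "gaussian"),
                         level, seed) {
  stopifnot(inherits(net, "correlation_network"))
  kind <- match.arg(kind)
  if (level < 0) abort("`level` must be nonnegative.")
  if (kind != "gaussian" && level > 1) abort("Fractional `level` must be <= 1.")
  W <- net$weights
  n <- nrow(W)
  with_seed(seed, {
    if (kind == "edge_permute") {
      ut <- which(upper.tri(W) & W != 0)
      m <- round(level * length(ut))
      if (m > 0) {
        chosen <- sample(ut, m)
        free <- setdiff(which(upper.tri(W) & W == 0), chosen)
        m <- min(m, length(free))
        dest <- if (m > 0) sample(free, m) else integer(0)
        wts <- W[chosen]
        put <- function(lin, val) {
          rc <- arrayInd(lin, dim(W))
          W[rc] <<- val
          W[rc[, c(2, 1), drop = FALSE]] <<- val
        }
        put(chosen, 0)
        if (m > 0) put(dest, wts[seq_len(m)])
      }
    } else if (kind == "vertex_delete") {
      d <- round(level * n)
      if (d > 0) {
        del <- sample(n, d)
        W[del, ] <- 0
        W[, del] <- 0
      }
    } else {
      ut <- which(upper.tri(W) & W != 0)
      if (length(ut) > 0 && level > 0) {
        noise <- rnorm(length(ut), mean = 0, sd = level)
        rc <- arrayInd(ut, dim(W))
        W[rc] <- W[rc] + noise
        W[rc[, c(2, 1), drop = FALSE]] <- W[rc]
      }
    }
  })
  correlation_network(W, method = net$method, p_threshold = net$p_threshold,
                      source_name = net$source_name)
}

#' Recovery accuracy of planted changes
#'
#' The integration output is a ranked list (rank 1 = most conserved);
#' planted changed vertices should fall to the end. Accuracy is the
#' mean normalized rank of the changed vertices, `mean(rank / N)`:
#' about 1 when every changed vertex sits at the very bottom (exactly
#' `(N - (|D| - 1) / 2) / N`), and 0.5 in expectation when changed
#' vertices land uniformly at random.
#'
#' @param ranked A ranked tibble from [rank_genes()] (columns `gene`,
#'   `rank`).
#' @param changed_set Character vector of planted changed gene
#'   identifiers (non-empty, all present in `ranked`).
#' @return Accuracy in (0, 1\].
#' @export
accuracy <- function(ranked, changed_set) {
  stopifnot(all(c("gene", "rank") %in% names(ranked)))
  if (length(changed_set) == 0) abort("`changed_set` must be non-empty.")
  if (!all(changed_set %in% ranked$gene)) {
    abort("All changed vertices must appear in the ranked list.")
  }
  N <- nrow(ranked)
  r <- ranked$rank[match(changed_set, ranked$gene)]
  mean(r / N)
}

#' Specify a robustness simulation
#'
#' Defaults state the benchmark's reference conditions: 5% planted
#' vertex changes on Barabási–Albert networks with 2 attachment edges,
#' and noise sweeps of 0–50% (edge permutation, vertex deletion) or
#' sigma 0–6 (Gaussian).
#'
#' @param n_vertices Network size (default 100).
#' @param attach_m BA attachment edges per vertex (default 2).
#' @param changed_fraction Planted change fraction (default 0.05).
#' @param n_networks Number of data sources, 2 or 3 (may be a vector
#'   to sweep both).
#' @param noise_kind One or more of `"edge_permute"`,
#'   `"vertex_delete"`, `"gaussian"`.
#' @param noise_levels Numeric vector of levels; defaults per kind
#'   (fractions `seq(0, 0.5, 0.1)`, or sigma `0:6` for `gaussian`).
#' @param mode Similarity mode(s), `"local"` and/or `"global"`.
#' @param n_replicates Independent replicates per condition (default
#'   20).
#' @param restart_prob RWR restart probability for global mode.
#' @param seed Integer master seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_vertices = 100, attach_m = 2,
                            changed_fraction = 0.05, n_networks = 2,
                            noise_kind = "gaussian", noise_levels = NULL,
                            mode = "global", n_replicates = 20,
                            restart_prob = 0.4, seed = 1) {
  noise_kind <- match.arg(noise_kind,
                          c("edge_permute", "vertex_delete", "gaussian"),
                          several.ok = TRUE)
  stopifnot(all(mode %in% c("local", "global")),
            all(n_networks %in% c(2, 3)))
  if (is.null(noise_levels)) {
    noise_levels <- if (identical(noise_kind, "gaussian")) 0:6 else seq(0, 0.5, 0.1)
  }
  structure(list(n_vertices = n_vertices, attach_m = attach_m,
                 changed_fraction = changed_fraction,
                 n_networks = n_networks, noise_kind = noise_kind,
                 noise_levels = noise_levels, mode = mode,
                 n_replicates = n_replicates, restart_prob = restart_prob,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Run the planted-change robustness benchmark
#'
#' For every combination of noise kind, noise level, number of data
#' sources, and replicate: generate a base scale-free network, plant
#' changes, give every data source its own independent noise draw, run
#' pairwise vertex similarity, join scores (arithmetic mean; identity
#' for a single pair), rank, and score recovery [accuracy()]. Both
#' similarity modes are evaluated on the same perturbed instance so
#' mode comparisons are paired. Bit-for-bit reproducible from the spec
#' seed.
#'
#' @param spec A [simulation_spec()].
#' @param verbose Log progress to stderr.
#' @return A long-format tibble (class `benchmark_result`) with
#'   columns `kind`, `level`, `n_networks`, `mode`, `replicate`,
#'   `accuracy`.
#' @export
run_benchmark <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  grid <- expand.grid(kind = spec$noise_kind, level = spec$noise_levels,
                      n_networks = spec$n_networks,
                      replicate = seq_len(spec$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[!(grid$kind != "gaussian" & grid$level > 1), , drop = FALSE]
  seeds <- with_seed(spec$seed, {
    matrix(sample.int(.Machine$integer.max - 1, nrow(grid) * 3),
           ncol = 3)
  })
  cfg <- rwr_config(restart_prob = spec$restart_prob)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    base <- generate_ba_network(spec$n_vertices, spec$attach_m,
                                seed = seeds[i, 1])
    inst <- plant_changes(base, spec$changed_fraction, g$n_networks,
                          seed = seeds[i, 2])
    noise_seeds <- with_seed(seeds[i, 3], {
      sample.int(.Machine$integer.max - 1, g$n_networks)
    })
    nets <- lapply(seq_len(g$n_networks), function(j) {
      inject_noise(inst$networks[[j]], kind = g$kind, level = g$level,
                   seed = noise_seeds[j])
    })
    accs <- vapply(spec$mode, function(md) {
      sim <- pairwise_similarity(nets, md, cfg)
      joined <- join_scores(sim$pairs,
                            method = if (length(sim$pairs) == 1) "identity" else "mean")
      accuracy(rank_genes(joined), inst$changed)
    }, numeric(1))
    rows[[i]] <- tibble(kind = g$kind, level = g$level,
                        n_networks = g$n_networks, mode = spec$mode,
                        replicate = g$replicate, accuracy = unname(accs))
    if (verbose && i %% 25 == 0) {
      message(sprintf("[benchmark] %d/%d conditions done", i, nrow(grid)))
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("benchmark_result", class(out))
  out
}

#' Summarise a benchmark run
#'
#' Mean and spread of recovery accuracy per condition.
#'
#' @param x A `benchmark_result` tibble from [run_benchmark()].
#' @param ... Unused.
#' @return A tibble with one row per (kind, level, n_networks, mode).
#' @exportS3Method
glance.benchmark_result <- function(x, ...) {
  x |>
    group_by(.data$kind, .data$level, .data$n_networks, .data$mode) |>
    summarise(mean_accuracy = mean(.data$accuracy),
              sd_accuracy = sd(.data$accuracy),
              n_replicates = n(), .groups = "drop")
}
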
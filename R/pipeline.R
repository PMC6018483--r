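#' Differential (or non-differential) integration of data sources
#'
#' End-to-end pipeline: one significance-thresholded correlation
#' interactome per data source (abundance vectors pool the samples of
#' both phenotypes in fixed order), universe alignment, pairwise vertex
#' similarity (local or global), joining (identity for two sources,
#' else the chosen function), and BCa confidence intervals on each
#' gene's final cosine. A high score marks a gene whose network
#' neighborhood is conserved across sources; with two pooled phenotypes
#' it additionally marks phenotype-discriminating structure.
#'
#' @param tables List of two or more [abundance_table()]s (one per data
#'   source).
#' @param phenotypes `NULL` for non-differential integration on all
#'   samples; one label for non-differential integration of that
#'   phenotype; two labels for differential integration (each source
#'   must carry >= 3 samples of each label).
#' @param mode `"local"` or `"global"` vertex similarity.
#' @param method Correlation method for network construction.
#' @param p_threshold Edge significance threshold (default 0.05).
#' @param join Joining function over pairwise score vectors; `"auto"`
#'   (default) uses identity for two sources and the arithmetic mean
#'   otherwise.
#' @param align Gene-universe alignment mode (default
#'   `"intersection"`).
#' @param rwr [rwr_config()] for global mode.
#' @param bootstrap A [bootstrap_config()] to attach BCa confidence
#'   intervals, or `NULL` to skip them (CI columns are `NA`).
#'   Intervals are only defined for two sources, where the final score
#'   is itself a cosine.
#' @param keep_diagonal Passed to [build_correlation_network()].
#' @param verbose Log per-stage timings and counts to stderr.
#' @return A `similarity_result` tibble with columns `gene`, `score`,
#'   `ci_low`, `ci_high`, `ci_width`, ordered by the input gene index;
#'   pass to [rank_genes()] for the ranked biomarker list.
#' @export
differential_integrate <- function(tables,
                                   phenotypes = NULL,
                                   mode = c("local", "global"),
                                   method = c("spearman", "pearson"),
                                   p_threshold = 0.05,
                                   join = c("auto", "mean", "max", "min",
                                            "geometric_mean", "identity"),
                                   align = c("intersection", "union"),
                                   rwr = rwr_config(),
                                   bootstrap = NULL,
                                   keep_diagonal = FALSE,
                                   verbose = FALSE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  join <- match.arg(join)
  align <- match.arg(align)
  stopifnot(is.list(tables), length(tables) >= 2)
  walk(tables, function(t) stopifnot(inherits(t, "abundance_table")))

  if (!is.null(phenotypes)) {
    if (length(phenotypes) > 2) abort("At most two phenotype labels.")
    tables <- lapply(tables, subset_phenotypes, phenotypes = phenotypes)
    if (length(phenotypes) == 2) {
      walk(tables, function(t) {
        counts <- table(t$phenotype)
        if (any(counts[phenotypes] < 3)) {
          abort(sprintf(
            "Differential mode needs >= 3 samples per phenotype in source '%s'.",
            t$source_name))
        }
      })
    }
  }

  stage <- stage_logger(verbose)
  nets <- lapply(tables, build_correlation_network, method = method,
                 p_threshold = p_threshold, keep_diagonal = keep_diagonal)
  stage("network construction", sprintf(
    "edges kept: %s",
    paste(vapply(nets, function(n) sum(n$weights != 0) / 2, numeric(1)),
          collapse = "/")))

  nets <- align_gene_universe(nets, mode = align)
  genes <- nets[[1]]$gene_ids
  stage("universe alignment", sprintf("genes: %d", length(genes)))

  sim <- pairwise_similarity(nets, mode, rwr)
  stage("vertex similarity", sprintf("pairs: %d", length(sim$pairs)))

  join_method <- if (join == "auto") {
    if (length(sim$pairs) == 1) "identity" else "mean"
  } else join
  result <- join_scores(sim$pairs, method = join_method)
  result$ci_low <- NA_real_
  result$ci_high <- NA_real_
  result$ci_width <- NA_real_

  if (!is.null(bootstrap)) {
    if (length(sim$pairs) == 1) {
      result <- attach_ci_rows(result, sim$row_mats[[1]][[1]],
                               sim$row_mats[[1]][[2]], bootstrap)
      stage("BCa bootstrap", sprintf("replicates: %d", bootstrap$n_resamples))
    } else {
      inform(paste("Confidence intervals are only defined for two data",
                   "sources (the final score is then a single cosine);",
                   "CI columns left NA."))
    }
  }

  attr(result, "mode") <- mode
  attr(result, "method") <- method
  attr(result, "sources") <- vapply(tables, function(t) t$source_name,
                                    character(1))
  attr(result, "phenotypes") <- phenotypes
  class(result) <- c("similarity_result", class(result))
  result
}

# All pairwise score vectors plus, per pair, the two row matrices that
# fed the final cosine (needed for bootstrap CIs).
pairwise_similarity <- function(nets, mode, rwr) {
  idx <- combn(length(nets), 2)
  mats <- if (mode == "global") {
    lapply(nets, function(n) stationary_profile(n, rwr)$dist)
  } else {
    lapply(nets, function(n) n$weights)
  }
  pairs <- lapply(seq_len(ncol(idx)), function(k) {
    a <- idx[1, k]; b <- idx[2, k]
    pair_scores(nets[[a]]$gene_ids, row_cosine(mats[[a]], mats[[b]]), mode)
  })
  row_mats <- lapply(seq_len(ncol(idx)), function(k) {
    list(mats[[idx[1, k]]], mats[[idx[2, k]]])
  })
  list(pairs = pairs, row_mats = row_mats)
}

stage_logger <- function(verbose) {
  t0 <- Sys.time()
  function(name, detail = "") {
    if (verbose) {
      message(sprintf("[%s] %.2fs %s", name,
                      as.numeric(Sys.time() - t0, units = "secs"), detail))
    }
    t0 <<- Sys.time()
    invisible(NULL)
  }
}

#' Assemble integration runs into a comparison matrix
#'
#' Stacks several integration results (e.g. the intra- and inter-cancer
#' comparisons of a pan-cancer analysis) into one comparisons-by-genes
#' score matrix plus the matching CI-width matrix, the substrate for
#' [compare_integrations()] and [detect_outlier_biomarkers()].
#'
#' @param results Named list of `similarity_result` tibbles (names are
#'   comparison labels, e.g. `"basal_vs_luminalA"`) over one common
#'   gene set.
#' @return An object of class `comparison_matrix` with fields
#'   `comparison_labels`, `gene_ids`, `scores`, `ci_widths`.
#' @export
comparison_matrix <- function(results) {
  stopifnot(is.list(results), length(results) >= 2)
  if (is.null(names(results)) || anyDuplicated(names(results))) {
    abort("`results` must be a uniquely named list of comparisons.")
  }
  genes <- sort(results[[1]]$gene)
  walk(results, function(r) {
    if (!identical(sort(r$gene), genes)) {
      abort("All comparisons must cover the same gene set.")
    }
  })
  scores <- t(vapply(results, function(r) r$score[match(genes, r$gene)],
                     numeric(length(genes))))
  widths <- t(vapply(results, function(r) {
    w <- if ("ci_width" %in% names(r)) r$ci_width else rep(NA_real_, nrow(r))
    w[match(genes, r$gene)]
  }, numeric(length(genes))))
  dimnames(scores) <- dimnames(widths) <- list(names(results), genes)
  structure(list(comparison_labels = names(results), gene_ids = genes,
                 scores = scores, ci_widths = widths),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("<comparison_matrix> %d comparisons x %d genes\n",
              length(x$comparison_labels), length(x$gene_ids)))
  invisible(x)
}

#' Spearman correlation between integration runs
#'
#' The relationship between two integration analyses is the Spearman
#' correlation between their per-gene similarity score vectors, with
#' all genes included. A comparison with a constant score vector has
#' undefined rank correlation; its entries are set to 0 with a warning.
#'
#' @param cm A [comparison_matrix()].
#' @return Symmetric correlation matrix with unit diagonal, labelled by
#'   comparison.
#' @export
compare_integrations <- function(cm) {
  stopifnot(inherits(cm, "comparison_matrix"))
  if (length(cm$comparison_labels) < 2) abort("Need >= 2 comparisons.")
  const <- apply(cm$scores, 1, function(v) sd(v) == 0)
  rho <- suppressWarnings(stats::cor(t(cm$scores), method = "spearman"))
  if (any(const)) {
    warn(sprintf("Constant score vector(s), correlations set to 0: %s",
                 paste(cm$comparison_labels[const], collapse = ", ")))
  }
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  rho
}

#' Hierarchically cluster integration comparisons
#'
#' Agglomerative clustering of comparisons at distance `1 - rho`
#' (Spearman correlation from [compare_integrations()]), average
#' linkage by default. The result is a standard `hclust` object (a
#' rooted binary dendrogram) that can be cut at a height with
#' [cut_clusters()] or exported to Newick with [write_newick()].
#'
#' @param rho Symmetric correlation matrix with comparison labels.
#' @param linkage Linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An `hclust` object (class also `comparison_dendrogram`).
#' @export
cluster_comparisons <- function(rho, linkage = "average") {
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  d <- as.dist(1 - rho)
  hc <- hclust(d, method = linkage)
  class(hc) <- c("comparison_dendrogram", class(hc))
  hc
}

#' Cut a comparison dendrogram at a height
#'
#' @param tree An `hclust`/`comparison_dendrogram`.
#' @param h Cut height on the `1 - rho` distance scale.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(tree, h) {
  cutree(structure(unclass(tree), class = "hclust"), h = h)
}

#' Export a dendrogram to Newick
#'
#' Branch lengths are merge-height differences (via
#' [ape::as.phylo()]).
#'
#' @param tree An `hclust` or `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ph <- as_phylo_tree(tree)
  ape::write.tree(ph, file = path)
  invisible(path)
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (inherits(tree, "comparison_dendrogram")) {
    class(tree) <- "hclust"
  }
  if (inherits(tree, "hclust")) return(ape::as.phylo(tree))
  abort("`tree` must be an hclust or phylo object.")
}

#' Call outlier biomarkers from a comparison matrix
#'
#' A gene is a putative biomarker of a comparison when its score there
#' is an outlier of that gene's own score distribution across all
#' comparisons. Procedure: (1) z-score each comparison (column
#' normalization across all genes, so each comparison's scale is
#' removed before any filtering); (2) drop genes whose CI width
#' exceeds `ci_width_max` in any comparison (low-confidence scores);
#' (3) per gene, flag comparisons outside the Tukey fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of its values across comparisons
#' (quartiles by linear interpolation, [stats::quantile()] type 7);
#' (4) genes with at least one flag are reported, with their surviving
#' values re-normalized row-wise.
#'
#' A gene scored identically across all comparisons has zero IQR and no
#' strict outlier, hence no call. Fewer than 4 comparisons make the
#' quartiles unstable and are rejected.
#'
#' @param cm A [comparison_matrix()] carrying scores and CI widths.
#' @param ci_width_max Maximum tolerated CI width (default 0.04).
#' @return A tibble of calls with columns `gene`, `comparison`,
#'   `direction` (`"high"`/`"low"`), `normalized_score` (the row
#'   z-score of the flagged cell).
#' @export
detect_outlier_biomarkers <- function(cm, ci_width_max = 0.04) {
  stopifnot(inherits(cm, "comparison_matrix"))
  if (!is.numeric(ci_width_max) || ci_width_max <= 0) {
    abort("`ci_width_max` must be positive.")
  }
  n_comp <- length(cm$comparison_labels)
  if (n_comp < 4) {
    abort("Need at least 4 comparisons for stable quartile fences.")
  }
  Zfull <- t(apply(cm$scores, 1, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(Zfull) <- dimnames(cm$scores)

  w <- cm$ci_widths
  keep <- apply(w, 2, function(col) all(is.na(col)) || all(col <= ci_width_max, na.rm = TRUE))
  Z <- Zfull[, keep, drop = FALSE]
  if (ncol(Z) == 0) return(empty_biomarker_calls())

  calls <- list()
  for (g in seq_len(ncol(Z))) {
    v <- Z[, g]
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    # strict fences with a floating-point guard so a numerically
    # constant row (zero IQR up to rounding) yields no call
    tol <- 1e-8 * max(1, abs(q))
    lo <- q[1] - 1.5 * iqr - tol
    hi <- q[2] + 1.5 * iqr + tol
    out <- which(v < lo | v > hi)
    if (length(out) > 0) {
      rz <- (v - mean(v)) / sd(v)  # row renormalization for reporting
      calls[[length(calls) + 1]] <- tibble(
        gene = colnames(Z)[g],
        comparison = unname(cm$comparison_labels[out]),
        direction = unname(ifelse(v[out] > hi, "high", "low")),
        normalized_score = unname(rz[out])
      )
    }
  }
  if (length(calls) == 0) return(empty_biomarker_calls())
  bind_rows(calls) |> arrange(.data$gene, .data$comparison)
}

empty_biomarker_calls <- function() {
  tibble(gene = character(), comparison = character(),
         direction = character(), normalized_score = numeric())
}
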
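#' Construct a correlation network object
#'
#' Low-level constructor wrapping a symmetric weighted adjacency matrix
#' over an ordered gene index. Most users build networks with
#' [build_correlation_network()] or [load_network()].
#'
#' @param weights Symmetric numeric matrix with identical row/column
#'   gene identifiers.
#' @param method Correlation method that produced the weights
#'   (`"pearson"`, `"spearman"`, or `NA` for pre-made/simulated
#'   networks).
#' @param p_threshold Significance threshold used during construction
#'   (`NA` when not applicable).
#' @param source_name Free-text data-source name.
#' @param check_range If `TRUE`, assert all weights lie in \[-1, 1\]
#'   (true for correlation networks; pre-made or noise-injected
#'   networks may exceed it).
#' @return An object of class `correlation_network`.
#' @export
correlation_network <- function(weights, method = NA_character_,
                                p_threshold = NA_real_,
                                source_name = "network",
                                check_range = FALSE) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    abort("`weights` must be a numeric matrix.")
  }
  if (nrow(weights) != ncol(weights)) abort("Adjacency matrix must be square.")
  if (is.null(rownames(weights))) {
    rownames(weights) <- colnames(weights) <- paste0("g", seq_len(nrow(weights)))
  }
  if (!identical(rownames(weights), colnames(weights))) {
    abort("Row and column gene identifiers must match.")
  }
  if (anyDuplicated(rownames(weights))) abort("Duplicated gene identifiers.")
  if (max(abs(weights - t(weights))) > 1e-12) {
    abort("Adjacency matrix must be symmetric.")
  }
  weights <- (weights + t(weights)) / 2  # enforce exact symmetry
  if (check_range && any(weights < -1 - 1e-12 | weights > 1 + 1e-12)) {
    abort("Correlation weights must lie in [-1, 1].")
  }
  structure(
    list(
      gene_ids = rownames(weights),
      weights = weights,
      method = method,
      p_threshold = p_threshold,
      source_name = source_name
    ),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<correlation_network> %s: %d genes, %d edges (method: %s, p < %s)\n",
              x$source_name, length(x$gene_ids), nz,
              x$method, format(x$p_threshold)))
  invisible(x)
}

#' Build a significance-thresholded correlation interactome
#'
#' Each gene product is a vertex; the edge weight between two genes is
#' the correlation between their abundance vectors, kept only when its
#' two-sided p-value falls below `p_threshold` and set to zero
#' otherwise. For differential integration the abundance vector of a
#' gene concatenates the samples of both phenotypes (see
#' [subset_phenotypes()]); correlations are computed on the pooled
#' vector.
#'
#' p-values are asymptotic and uncorrected: the t-approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' with Spearman treated by the same large-sample approximation on the
#' rank correlation. Missing entries are handled pairwise; a gene pair
#' with fewer than 3 complete observations gets edge 0. Constant rows
#' have undefined correlation: all their edges are set to 0 with a
#' warning.
#'
#' @param table An [abundance_table()] (at least 3 samples).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param p_threshold Two-sided p-value threshold in (0, 1\]; the
#'   conventional default is 0.05.
#' @param keep_diagonal Self-correlation is identically 1 with p ~ 0,
#'   which would add a constant coordinate to every neighbor vector;
#'   by default the diagonal is zeroed so similarity reflects
#'   neighbors only. Set `TRUE` to retain the literal diagonal of 1.
#' @return A [correlation_network()].
#' @export
#' @examples
#' m <- matrix(rnorm(50), 5, 10,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
#' net <- build_correlation_network(abundance_table(m), method = "pearson",
#'                                  p_threshold = 0.2)
build_correlation_network <- function(table,
                                      method = c("spearman", "pearson"),
                                      p_threshold = 0.05,
                                      keep_diagonal = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  method <- match.arg(method)
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    abort("`p_threshold` must lie in (0, 1].")
  }
  X <- table$values
  if (ncol(X) < 3) abort("At least 3 samples are required to correlate.")

  obs <- !is.na(X)
  n_pair <- tcrossprod(obs * 1)           # pairwise-complete counts
  r <- suppressWarnings(
    stats::cor(t(X), method = method, use = "pairwise.complete.obs")
  )

  const <- apply(X, 1, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0 || sd(v) == 0
  })
  if (any(const)) {
    warn(sprintf("Constant abundance row(s), edges set to 0: %s",
                 paste(head(table$gene_ids[const], 5), collapse = ", ")))
  }

  p <- correlation_p_value(r, n_pair)
  A <- r
  A[is.na(A)] <- 0
  A[!(p < p_threshold)] <- 0              # NA p (undefined) also zeroed
  A[n_pair < 3] <- 0
  diag(A) <- if (keep_diagonal) 1 else 0
  A <- (A + t(A)) / 2
  dimnames(A) <- list(table$gene_ids, table$gene_ids)

  correlation_network(A, method = method, p_threshold = p_threshold,
                      source_name = table$source_name, check_range = TRUE)
}

# Two-sided asymptotic p-value of a correlation matrix given
# pairwise-complete sample counts. |r| = 1 maps to p = 0.
correlation_p_value <- function(r, n) {
  p <- matrix(NA_real_, nrow(r), ncol(r))
  ok <- !is.na(r) & n >= 3
  rr <- pmin(pmax(r[ok], -1), 1)
  nn <- n[ok]
  tstat <- ifelse(abs(rr) >= 1, Inf, abs(rr) * sqrt((nn - 2) / (1 - rr^2)))
  p[ok] <- 2 * stats::pt(tstat, df = nn - 2, lower.tail = FALSE)
  p
}

#' Load a pre-made network from a 3-column edge list
#'
#' Reads an undirected weighted edge list (TSV columns `gene_a`,
#' `gene_b`, `weight`; a header row is accepted and detected) into a
#' symmetric adjacency. Listing an edge in either or both orientations
#' gives the same network. Self-loops are dropped with a warning;
#' duplicate edges with contradictory weights are an error.
#'
#' @param path Path to the edge-list TSV.
#' @param gene_universe Optional character vector fixing the ordered
#'   gene index; defaults to the sorted union of listed genes. Pairs
#'   not listed get weight 0.
#' @param source_name Data-source name for the network.
#' @return A [correlation_network()] (method `NA`).
#' @export
load_network <- function(path, gene_universe = NULL, source_name = NULL) {
  first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  has_header <- ncol(first) >= 3 && is.na(suppressWarnings(as.numeric(first[[3]])))
  df <- readr::read_tsv(path, col_names = c("gene_a", "gene_b", "weight"),
                        skip = if (has_header) 1 else 0,
                        col_types = "ccd", progress = FALSE)
  edge_list_to_network(df, gene_universe = gene_universe,
                       source_name = source_name %||% basename(path))
}

edge_list_to_network <- function(df, gene_universe = NULL,
                                 source_name = "network") {
  loops <- df$gene_a == df$gene_b
  if (any(loops)) {
    warn(sprintf("Dropped %d self-loop(s).", sum(loops)))
    df <- df[!loops, , drop = FALSE]
  }
  key <- ifelse(df$gene_a < df$gene_b,
                paste(df$gene_a, df$gene_b, sep = "\r"),
                paste(df$gene_b, df$gene_a, sep = "\r"))
  dup <- split(df$weight, key)
  contradictory <- vapply(dup, function(w) max(w) - min(w) > 1e-12, logical(1))
  if (any(contradictory)) {
    pair <- strsplit(names(dup)[contradictory][1], "\r")[[1]]
    abort(sprintf("Contradictory duplicate edge weights for pair (%s, %s).",
                  pair[1], pair[2]))
  }
  genes <- gene_universe %||% sort(unique(c(df$gene_a, df$gene_b)))
  unknown <- setdiff(unique(c(df$gene_a, df$gene_b)), genes)
  if (length(unknown) > 0) {
    abort(sprintf("Edge list references gene(s) outside the universe: %s.",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  A <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  if (nrow(df) > 0) {
    ia <- match(df$gene_a, genes)
    ib <- match(df$gene_b, genes)
    A[cbind(ia, ib)] <- df$weight
    A[cbind(ib, ia)] <- df$weight
  }
  correlation_network(A, source_name = source_name)
}

#' Write a network as a 3-column edge list
#'
#' Each undirected nonzero edge is written once (`gene_a` < `gene_b`
#' in index order) as TSV columns `gene_a`, `gene_b`, `weight`.
#'
#' @param net A [correlation_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  readr::write_tsv(tidy(net), path, progress = FALSE)
  invisible(path)
}

#' Align several networks onto one shared gene universe
#'
#' Vertex similarity compares networks position-by-position, so all
#' networks must share one ordered gene index. `intersection`
#' (default, conservative) restricts every network to the genes present
#' in all of them, in the first network's order. `union` zero-pads the
#' rows/columns of genes a source lacks, which emulates a gene
#' unmeasured by that assay.
#'
#' @param networks List of at least two [correlation_network()]s.
#' @param mode `"intersection"` or `"union"`.
#' @return List of networks sharing one ordered gene index.
#' @export
align_gene_universe <- function(networks, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  stopifnot(length(networks) >= 2)
  walk(networks, function(n) stopifnot(inherits(n, "correlation_network")))
  ids <- lapply(networks, function(n) n$gene_ids)
  genes <- if (mode == "intersection") {
    common <- Reduce(intersect, ids)
    if (length(common) == 0) abort("Gene universes have empty intersection.")
    ids[[1]][ids[[1]] %in% common]
  } else {
    Reduce(union, ids)
  }
  lapply(networks, function(n) {
    A <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
    present <- intersect(genes, n$gene_ids)
    A[present, present] <- n$weights[present, present]
    correlation_network(A, method = n$method, p_threshold = n$p_threshold,
                        source_name = n$source_name)
  })
}

#' @exportS3Method
tidy.correlation_network <- function(x, ...) {
  ut <- which(upper.tri(x$weights) & x$weights != 0, arr.ind = TRUE)
  tibble(
    gene_a = x$gene_ids[ut[, 1]],
    gene_b = x$gene_ids[ut[, 2]],
    weight = x$weights[ut]
  ) |> arrange(.data$gene_a, .data$gene_b)
}

#' @exportS3Method
glance.correlation_network <- function(x, ...) {
  n <- length(x$gene_ids)
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  tibble(
    n_genes = n,
    n_edges = nz,
    density = if (n > 1) nz / (n * (n - 1) / 2) else NA_real_,
    n_isolated = sum(rowSums(x$weights != 0) == 0),
    method = x$method,
    p_threshold = x$p_threshold,
    source_name = x$source_name
  )
}
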
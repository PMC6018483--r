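#' Clumpiness of labels on a dendrogram
#'
#' Quantifies how aggregated each pair of leaf labels is within a
#' rooted binary tree (e.g. the dendrogram of integration comparisons,
#' with labels the cancer types involved). For labels a and b,
#' clumpiness is the mean of `1 / d(x, y)` over leaf pairs (x labelled
#' a, y labelled b, x != y), where `d` counts edges on the leaf-to-leaf
#' path; the mean is normalized by 1/2 (the minimum binary-tree leaf
#' distance is 2, a cherry) so values lie in (0, 1\]. High values mean
#' the two labels co-locate in subtrees; low values mean they are
#' dispersed. Branch lengths are ignored: the measure reflects cluster
#' structure only.
#'
#' The diagonal uses within-label pairs and needs at least 2 leaves
#' per label; a single-leaf label's diagonal entry is `NA`.
#'
#' @param tree An `hclust`/`comparison_dendrogram` or `phylo` tree.
#' @param labels Leaf labelling: named character vector (names are
#'   leaf tip labels) or a 2-column data frame (leaf, label).
#' @return A symmetric label-by-label matrix of class
#'   `clumpiness_matrix` with entries in (0, 1\] (`NA` on undefined
#'   diagonal entries).
#' @export
#' @examples
#' hc <- hclust(dist(c(a1 = 0, a2 = 0.1, b1 = 5, b2 = 5.1)), "average")
#' clumpiness(hc, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
clumpiness <- function(tree, labels) {
  ph <- as_phylo_tree(tree)
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  tips <- ph$tip.label
  missing <- setdiff(tips, names(labels))
  if (length(missing) > 0) {
    abort(sprintf("Unlabelled leaf/leaves: %s.",
                  paste(head(missing, 5), collapse = ", ")))
  }
  lab <- labels[tips]
  ph$edge.length <- rep(1, nrow(ph$edge))   # count edges, not heights
  D <- ape::cophenetic.phylo(ph)
  D <- D[tips, tips]
  ulab <- sort(unique(lab))
  V <- matrix(NA_real_, length(ulab), length(ulab),
              dimnames = list(ulab, ulab))
  for (i in seq_along(ulab)) {
    for (j in i:length(ulab)) {
      xi <- which(lab == ulab[i])
      xj <- which(lab == ulab[j])
      d <- D[xi, xj, drop = FALSE]
      vals <- if (i == j) {
        if (length(xi) < 2) numeric(0) else 1 / d[upper.tri(d)]
      } else {
        1 / as.vector(d)
      }
      V[i, j] <- V[j, i] <- if (length(vals) == 0) NA_real_ else 2 * mean(vals)
    }
  }
  structure(V, class = c("clumpiness_matrix", "matrix"))
}

#' @export
print.clumpiness_matrix <- function(x, ...) {
  cat("<clumpiness_matrix>\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' @exportS3Method
tidy.clumpiness_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame.table(m, responseName = "clumpiness",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(label_a = "Var1", label_b = "Var2")
}
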
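#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_ribbon geom_tile labs scale_fill_gradient theme_minimal
#'   facet_grid stat_summary
NULL

#' @export
ggplot2::autoplot

#' Plot a ranked similarity result
#'
#' Score against rank with the BCa confidence band (when present):
#' the ranked-order biomarker list at a glance.
#'
#' @param object A `similarity_result` tibble from
#'   [differential_integrate()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.similarity_result <- function(object, ...) {
  ranked <- rank_genes(object)
  p <- ggplot(ranked, aes(x = .data$rank, y = .data$score))
  if (!all(is.na(ranked$ci_low))) {
    p <- p + geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey80")
  }
  p + geom_line(colour = "steelblue") +
    labs(x = "rank (1 = most conserved)", y = "similarity score",
         title = "Ranked gene-product similarity") +
    theme_minimal()
}

#' Plot benchmark accuracy curves
#'
#' Mean recovery accuracy against noise level, one line per similarity
#' mode, faceted by noise kind and number of data sources — the
#' robustness-study summary view.
#'
#' @param object A `benchmark_result` tibble from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.benchmark_result <- function(object, ...) {
  ggplot(object, aes(x = .data$level, y = .data$accuracy,
                     colour = .data$mode)) +
    stat_summary(fun = mean, geom = "line") +
    stat_summary(fun = mean, geom = "point") +
    facet_grid(n_networks ~ kind, scales = "free_x",
               labeller = ggplot2::label_both) +
    labs(x = "noise level", y = "mean accuracy") +
    theme_minimal()
}

#' Plot a clumpiness matrix
#'
#' Label-by-label heatmap; darker tiles mark label pairs aggregated in
#' the same subtrees of the dendrogram.
#'
#' @param object A `clumpiness_matrix` from [clumpiness()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.clumpiness_matrix <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$label_a, y = .data$label_b,
                           fill = .data$clumpiness)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick",
                        na.value = "grey90", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "clumpiness") +
    theme_minimal()
}
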
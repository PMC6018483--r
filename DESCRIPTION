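Package: netconcord
Title: Differential Multi-Omics Integration via Network Node Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrates heterogeneous gene-product abundance data (for
    example transcriptome and proteome) by representing each data source
    as a significance-thresholded co-expression interactome and scoring
    each gene by how conserved its network neighborhood is across
    sources. Neighborhoods are compared either locally (cosine of
    one-hop edge-weight vectors) or globally (cosine of random-walk-
    with-restart stationary distributions). Pairwise scores are joined
    into a ranked biomarker list with bias-corrected and accelerated
    (BCa) bootstrap confidence intervals, and replicate runs are
    aggregated by rank product with permutation p-values. Downstream
    tools compare integration runs by Spearman correlation, cluster
    them hierarchically with Newick export, quantify label aggregation
    on the dendrogram (clumpiness), and call outlier biomarkers with
    Tukey fences. A scale-free-network simulation benchmark measures
    recovery of planted vertex changes under edge permutation, vertex
    deletion, and Gaussian edge noise.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
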
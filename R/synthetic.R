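#' Simulate a two-source, two-phenotype abundance data set
#'
#' Synthetic stand-in for paired transcriptome/proteome measurements of
#' two phenotypes, built from a shared module (co-expression block)
#' structure: each gene tracks its module's latent factor plus
#' independent noise, so genes of one module are strongly correlated.
#' A designated set of "changed" genes follows its own module in
#' source 1 but, in source 2, switches to a partner module in the
#' second phenotype's samples. Their pooled-sample correlation
#' neighborhoods therefore differ between sources, and differential
#' integration should place them at the bottom of the ranked list;
#' all other genes keep identical module membership in both sources.
#'
#' @param n_genes Number of genes (default 60).
#' @param module_size Genes per co-expression module (default 6).
#' @param n_changed Number of changed genes (default 10).
#' @param samples_per_phenotype Samples per phenotype per source
#'   (default 20).
#' @param noise_sd Within-gene residual standard deviation relative to
#'   the unit-variance module factor (default 0.4).
#' @param phenotypes Labels of the two phenotypes.
#' @param seed Integer seed.
#' @return A list with elements `tables` (list of two
#'   [abundance_table()]s named `source_a`, `source_b`) and `changed`
#'   (identifiers of the changed genes).
#' @export
simulate_abundance_pair <- function(n_genes = 60, module_size = 6,
                                    n_changed = 10,
                                    samples_per_phenotype = 20,
                                    noise_sd = 0.4,
                                    phenotypes = c("basal", "luminal"),
                                    seed) {
  if (missing(seed)) abort("`seed` is required.")
  stopifnot(n_changed < n_genes, module_size >= 2,
            length(phenotypes) == 2)
  n_modules <- ceiling(n_genes / module_size)
  if (n_modules < 2) abort("Need at least 2 modules; shrink `module_size`.")
  with_seed(seed, {
    genes <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
    module <- rep(seq_len(n_modules), each = module_size)[seq_len(n_genes)]
    changed <- sort(sample(n_genes, n_changed))
    partner <- (module[changed] %% n_modules) + 1  # a different module

    n_s <- samples_per_phenotype
    samples <- c(sprintf("%s_%02d", phenotypes[1], seq_len(n_s)),
                 sprintf("%s_%02d", phenotypes[2], seq_len(n_s)))
    pheno <- setNames(rep(phenotypes, each = n_s), samples)

    make_source <- function(swap) {
      # independent factor draws per source: assays measure the same
      # modules with independent sampling noise
      f <- matrix(rnorm(n_modules * 2 * n_s), n_modules, 2 * n_s)
      X <- f[module, , drop = FALSE]
      if (swap) {
        # changed genes follow the partner module in phenotype-2 samples
        ph2 <- n_s + seq_len(n_s)
        X[changed, ph2] <- f[partner, ph2, drop = FALSE]
      }
      X <- X + matrix(rnorm(n_genes * 2 * n_s, sd = noise_sd),
                      n_genes, 2 * n_s)
      dimnames(X) <- list(genes, samples)
      X
    }
    tables <- list(
      source_a = abundance_table(make_source(FALSE), phenotype = pheno,
                                 source_name = "source_a"),
      source_b = abundance_table(make_source(TRUE), phenotype = pheno,
                                 source_name = "source_b")
    )
    list(tables = tables, changed = genes[changed])
  })
}

#' Simulate a comparison matrix with planted biomarker spikes
#'
#' Synthetic stand-in for a pan-cancer collection of integration runs:
#' a comparisons-by-genes score matrix plus CI widths. A non-biomarker
#' gene scores at its own conservation level in every comparison;
#' spiked genes get one comparison shifted so far that its column
#' z-score exceeds `spike_z` in magnitude. A subset of spiked genes
#' additionally receives a wide confidence interval in the spiked
#' comparison, so only the CI-width filter (not the fence rule)
#' excludes them.
#'
#' Because Tukey fences are scale-free, any independent within-gene
#' noise would flag a fixed fraction of null genes no matter how small
#' the noise; and planted spikes distort per-comparison means and
#' standard deviations, which after column z-scoring would leak
#' systematic row variation into every gene. The generator therefore
#' constructs each comparison to have exactly equal mean and standard
#' deviation: the spiked genes' remaining entries absorb the spike's
#' moment distortion through a per-comparison affine correction. After
#' the biomarker rule's column z-scoring, null gene rows are exactly
#' constant (zero IQR, no call) and only planted spikes are outliers.
#' This is the idealized limit in which non-biomarker genes score
#' consistently; real score matrices carry within-gene noise, under
#' which the fences also flag incidental genes.
#'
#' @param n_genes Number of genes (default 200).
#' @param n_comparisons Number of integration comparisons (default 8).
#' @param n_spiked Spiked biomarker genes with narrow CIs (default
#'   10).
#' @param n_wide_ci Spiked genes with a wide CI (default 5).
#' @param spike_z Minimum |column z-score| of a spike (default 5).
#' @param ci_width_wide CI width given to wide-CI genes (default
#'   0.06, above the 0.04 filter).
#' @param seed Integer seed.
#' @return A list with `cm` (a [comparison_matrix()]), `spiked`
#'   (gene ids expected to be called), `wide_ci` (spiked gene ids
#'   expected to be excluded by the CI filter).
#' @export
simulate_comparison_matrix <- function(n_genes = 200, n_comparisons = 8,
                                       n_spiked = 10, n_wide_ci = 5,
                                       spike_z = 5, ci_width_wide = 0.06,
                                       seed) {
  if (missing(seed)) abort("`seed` is required.")
  n_special <- n_spiked + n_wide_ci
  stopifnot(n_special < n_genes - 2, n_special >= 2, n_comparisons >= 4)
  with_seed(seed, {
    genes <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
    comps <- sprintf("cmp%d", seq_len(n_comparisons))
    # Null spread is kept at half the column scale so the planted
    # spikes fit inside each comparison's (exactly shared) variance.
    gamma <- rnorm(n_genes, sd = 0.5)         # conservation level, z units
    special <- sample(n_genes, n_special)
    spiked <- sort(special[seq_len(n_spiked)])
    wide <- sort(special[n_spiked + seq_len(n_wide_ci)])
    null_idx <- setdiff(seq_len(n_genes), special)
    # near-balanced spike placement across comparisons
    spike_cmp <- sample(rep_len(seq_len(n_comparisons), n_special))
    spike_sign <- sample(c(-1, 1), n_special, replace = TRUE)
    spike_target <- (spike_z + 3) * spike_sign  # headroom over the threshold

    # Smaller matrices leave less per-column variance for the spikes;
    # shrink the null spread until every spike clears the threshold.
    V <- NULL
    for (shrink in c(1, 0.6, 0.36, 0.2, 0.1, 0.05)) {
      g_use <- gamma * shrink
      s1n <- sum(g_use[null_idx])
      s2n <- sum(g_use[null_idx]^2)
      Vc <- matrix(NA_real_, n_comparisons, n_genes,
                   dimnames = list(comps, genes))
      Vc[, null_idx] <- rep(g_use[null_idx], each = n_comparisons)
      ok <- TRUE
      for (ci in seq_len(n_comparisons)) {
        t <- g_use[special]
        here <- spike_cmp == ci
        t[here] <- spike_target[here]
        # v = a*t + b with column mean exactly 0 and sd exactly 1
        t1 <- sum(t); t2 <- sum(t^2); k <- n_special
        a2 <- ((n_genes - 1) - s2n - s1n^2 / k) / (t2 - t1^2 / k)
        if (!is.finite(a2) || a2 <= 0) {
          ok <- FALSE
          break
        }
        a <- sqrt(a2)
        b <- -(s1n + a * t1) / k
        Vc[ci, special] <- a * t + b
      }
      if (ok && all(abs(Vc[cbind(spike_cmp, special)]) >= spike_z)) {
        V <- Vc
        break
      }
    }
    if (is.null(V)) {
      abort("Cannot fit the requested spikes into the comparison variance; use more genes or fewer/smaller spikes.")
    }

    S <- 0.5 + 0.08 * V                       # one global affine map to a
    W <- matrix(runif(n_comparisons * n_genes, 0.005, 0.035),  # score-like scale
                n_comparisons, n_genes, dimnames = dimnames(S))
    wide_pos <- match(wide, special)
    W[cbind(spike_cmp[wide_pos], wide)] <- ci_width_wide

    results <- lapply(seq_len(n_comparisons), function(ci) {
      tibble(gene = genes, score = S[ci, ],
             ci_low = S[ci, ] - W[ci, ] / 2,
             ci_high = S[ci, ] + W[ci, ] / 2,
             ci_width = W[ci, ])
    })
    names(results) <- comps
    list(cm = comparison_matrix(results),
         spiked = genes[spiked], wide_ci = genes[wide])
  })
}
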
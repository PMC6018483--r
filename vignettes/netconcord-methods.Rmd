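---
title: "Methods: differential network integration in netconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential network integration in netconcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netconcord)
```

# The model

`netconcord` scores each gene by the conservation of its co-expression
neighborhood across data sources. The pipeline has three stages.

**1. Interactome construction.** For each source, gene pairs are
correlated across samples (Pearson or Spearman) and an edge keeps its
correlation as weight only when the two-sided p-value is below a
threshold (default 0.05); otherwise it is 0. In differential mode the
abundance vector of every gene concatenates the samples of both
phenotypes in a fixed order (first label's samples, then the
second's), so edges capture co-variation across the pooled phenotype
contrast. The key assumptions are the usual co-expression ones:
abundances are already normalized per source, samples are exchangeable
within phenotype, and marginal correlation (not partial correlation)
is an acceptable association measure.

**2. Vertex similarity.** Two networks over one aligned gene index are
compared per gene either locally — the cosine of the gene's two
edge-weight rows — or globally — the cosine of the gene's two
random-walk-with-restart stationary distributions
$s_z[i,\cdot] = \beta\, e(i)^{\top} (I - (1-\beta) W_z)^{-1}$,
computed by one linear solve per restart value rather than a per-seed
inverse. The local view is one hop; the global view diffuses over
multiple hops and is correspondingly smoother under edge-level noise.

**3. Joining and confidence.** With two sources the single pairwise
score vector is the result (identity join); with three, the pairwise
scores are combined elementwise, by arithmetic mean unless told
otherwise. Each final score, being a cosine between two vectors,
receives a bias-corrected and accelerated (BCa) bootstrap confidence
interval by resampling coordinate *pairs* of those two vectors — the
pairing of indices is always preserved, because independent resampling
of the two vectors would destroy exactly the concordance being
measured. The interval width is the confidence measure attached to the
gene; ranking is by descending score with ties broken by ascending
width, then gene identifier, so equal scores prefer the better-measured
gene and the ordering is total and reproducible.

# Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `p_threshold` | 0.05 | raw (uncorrected) two-sided edge significance; the conventional co-expression cutoff. Monotone: raising it only adds edges. |
| `method` | `"spearman"` | rank correlation is robust to monotone distortions between assay scales; `"pearson"` available. |
| `restart_prob` (β) | 0.4 | probability per step of teleporting back to the seed; the network-propagation convention. β→1 collapses the stationary distribution to the seed indicator (every shared vertex scores 1); small β diffuses widely. Per-vertex β is supported. |
| `n_resamples` | 1000 | bootstrap replicates; the permutation count for rank product defaults to 1000 as well. |
| `alpha` | 0.05 | two-sided miscoverage, i.e. 95% intervals. The interval level is a package choice; only the width is used downstream. |
| `resample_size` | full length | standard bootstrap; m-out-of-n subsampling available, but BCa theory is stated for the standard bootstrap, hence the default. |
| `linkage` | `"average"` | agglomeration on the 1 − ρ distance between integration runs; standard for correlation-derived distances and configurable. |
| `ci_width_max` | 0.04 | biomarker CI-width filter. |
| `changed_fraction` | 0.05 | benchmark planted-change fraction. |

# Numerical choices and degenerate inputs

* **Zero-vector cosine is 0.** The cosine is undefined for an all-zero
  vector; an isolated or unmeasured gene is treated as maximally
  non-conserved. This choice is what makes vertex deletion the most
  damaging benchmark noise, consistent with the missing-data reading.
* **Diagonal.** Self-correlation is identically 1 with p ≈ 0, which
  would add a constant coordinate to every neighbor vector and inflate
  all similarities; the diagonal is zeroed by default
  (`keep_diagonal = TRUE` restores the literal behavior).
* **Negative weights in the walk.** Transition mass uses |weight|
  (association strength drives diffusion regardless of sign; the sign
  still matters for local similarity). `negative = "clip"` discards
  negative edges instead.
* **Isolated vertices are absorbing** in the transition matrix so the
  resolvent stays well defined; their stationary distribution is their
  own indicator.
* **Constant abundance rows** have undefined correlation: all their
  edges are set to 0 with a warning. Gene pairs with fewer than 3
  pairwise-complete observations get edge 0.
* **BCa conventions.** Bootstrap quantiles are type-1 order statistics
  (`ceiling(p·B)`, clamped to [1, B]); the bias-correction proportion
  is clamped to [1/(2B), 1 − 1/(2B)] so its normal quantile stays
  finite; an all-equal replicate distribution yields a width-0
  interval at that value; the acceleration constant falls back to 0
  when the jackknife values are constant. A degenerate resample whose
  vectors are all-zero contributes statistic 0, per the zero-vector
  contract.
* **Quartiles** in the biomarker rule use linear interpolation
  (`stats::quantile` type 7) — Tukey fences are method-sensitive, so
  one convention is pinned and tested. The fence comparison carries a
  1e-8 tolerance so a row that is constant up to floating-point
  rounding (zero IQR) produces no call.
* **Rank-product p-values** use the +1 pseudocount estimator
  `(#{perm RP ≤ obs} + 1)/(n_perm + 1)`, bounded away from zero.

# Design choices where the design was open

* **Pooled-phenotype correlation.** Differential mode computes each
  correlation on the concatenated two-phenotype sample vector (not
  per-phenotype followed by contrast); this is the implemented reading
  of "m samples from one phenotype and n − m from another" and is what
  lets a phenotype-dependent rewiring appear as cross-source
  discordance.
* **Biomarker rule order.** Comparisons (columns) are z-scored on the
  full gene set first; the CI-width filter and the per-gene fences
  operate on those fixed normalized values, and surviving genes are
  re-normalized row-wise for reporting. Normalizing before filtering
  keeps the filter monotone: loosening `ci_width_max` can only add
  calls.
* **Confidence intervals for >2 sources** are undefined here: with a
  mean join the final score is no longer a single cosine, so the CI
  columns are `NA` and a message is emitted. The two-source case — the
  method's primary use — always has intervals.
* **Benchmark noise placement.** Every simulated data source,
  including the copy that plays the "first assay", receives its own
  independent noise draw: all assays are noisy, not just the derived
  ones.
* **Accuracy statistic.** Recovery is the mean normalized rank of the
  planted changed vertices, the simplest statistic with worst case 0.5
  under uniform placement and best case ≈ 1 when all changes sit at
  the bottom of the list.
* **Clumpiness formula.** The label-aggregation measure is fixed as
  the mean inverse leaf-to-leaf path length (edges counted, branch
  lengths ignored) normalized by the binary-tree minimum 1/2, giving
  values in (0, 1]. It is rotation-invariant, bounded, and isolated in
  its own module so an alternative aggregation measure can be swapped
  in without touching callers.
* **Universe alignment** defaults to intersection (the conservative
  choice of a single shared gene set); union zero-pads and exists to
  study missing-vertex effects.

# What the synthetic generators emulate — and what they do not

`simulate_abundance_pair()` builds two sources from shared latent
co-expression modules: each gene tracks its module factor plus noise,
and a designated set of "changed" genes follows a different module in
the second source's second-phenotype samples. This reproduces the
feature the method detects — cross-source, phenotype-linked rewiring —
but not the long-tailed abundance distributions, batch structure, or
uneven assay coverage of real transcriptome/proteome data. A green
test on it establishes that the pipeline orders planted rewiring below
conserved structure, not that real biomarkers will rank identically.

`simulate_comparison_matrix()` plants single-comparison spikes in a
pan-cancer-style score matrix. Because Tukey fences are scale-free,
*any* independent per-cell noise flags a fixed fraction of null genes
regardless of the noise's size, so a fixture in which only planted
spikes must be recovered exactly cannot carry iid row noise. Instead
the generator constructs every comparison with exactly equal mean and
standard deviation — the spiked genes' remaining entries absorb the
spikes' moment distortion via a per-comparison affine correction — so
that after the rule's own column z-scoring, non-biomarker rows are
exactly constant. This is the idealized limit of genes scoring
consistently across comparisons; on real matrices the fence rule will
also flag incidental genes, and the CI-width filter is doing real
work.

The benchmark's Barabási–Albert networks emulate hubs and scale-free
degree structure but are unweighted before noise; real interactomes
have correlated, bounded edge weights. Facet network sizes in the
original robustness study are not recoverable, so the benchmark
defaults to n = 100 (with sizes configurable); the study's own
observation that results are insensitive to network size motivates
treating one size as representative.

# Known limitations

* Correlation networks are marginal: no partial-correlation or
  mutual-information options, and no multiple-testing correction on
  edge p-values (by design, matching the raw threshold convention).
* The global walk uses the closed-form resolvent; simulated
  (Monte-Carlo) walks are out of scope.
* Dense matrix algebra throughout: comfortable to a few thousand
  genes; the full-transcriptome scale benefits from sparse solvers not
  implemented here.
* Clumpiness significance (permutation nulls) is not implemented; the
  measure is descriptive.
* Survival mining, gene-set enrichment, and raw-omics normalization
  are intentionally outside the package: inputs are normalized
  abundance tables or pre-made edge lists.
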
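# netconcord

Differential integration of multi-omics data by network node
similarity.

High-throughput assays such as RNA-seq transcriptomics and mass-
spectrometry proteomics measure the same genes with different
sensitivity and coverage, and transcript and protein abundances
correlate only weakly. `netconcord` integrates such heterogeneous data
sources without ever collapsing genes into clusters: each data source
becomes a co-expression interactome, and each gene is scored by how
conserved its network neighborhood is across sources. Pooling samples
from two phenotypes (say, basal vs. luminal breast tumors) before
network construction turns the same score into a *differential*
integration: genes ranked high have neighborhoods that are consistent
across assays while discriminating the phenotypes, which makes the top
of the list a shortlist of candidate biomarkers with per-gene
confidence. It is aimed at computational biologists doing multi-assay
tumor profiling, but applies to any pair (or triple) of abundance
matrices over a shared gene universe.

## The method

For each data source μ with abundance g<sub>μ</sub>(i, k) of gene i in
sample k, the interactome adjacency is the significance-thresholded
correlation

&nbsp;&nbsp;A<sub>μ</sub>[i, j] = ρ<sub>μ</sub>(i, j) if
p<sub>μ</sub>(i, j) &lt; 0.05, else 0,

with Pearson or Spearman ρ and two-sided asymptotic p-values. Each
gene is then compared between two networks in one of two ways:

* **local similarity** — the cosine C(x, y) = Σxᵢyᵢ / (‖x‖‖y‖)
  between the gene's one-hop edge-weight rows
  c<sub>μν</sub>[i] = C(A<sub>μ</sub>[i, ·], A<sub>ν</sub>[i, ·]);
* **global similarity** — the cosine between the gene's
  random-walk-with-restart stationary distributions
  s<sub>z</sub>[i, ·] = β (I − (1 − β) W<sub>z</sub>)⁻¹ e(i), where
  W<sub>z</sub> is the row-stochastic transition matrix of
  |A<sub>z</sub>| and β (default 0.4) is the restart probability.

With two sources the pairwise score is the final score; with more, a
joining function f (arithmetic mean by default) combines the pairwise
scores. Every score gets a bias-corrected and accelerated (BCa)
bootstrap confidence interval by resampling coordinate pairs of the
final cosine; the CI width is the score's confidence measure.
Replicate runs are aggregated by rank product with permutation
p-values. Downstream, collections of integration runs can be compared
by Spearman correlation, clustered (average linkage on 1 − ρ, Newick
export), summarized by dendrogram label *clumpiness*, and mined for
outlier biomarkers with Tukey fences (1.5×IQR) after z-normalization,
filtering out genes with CI widths above 0.04.

A built-in benchmark reproduces the method's robustness study:
Barabási–Albert networks with 5% of vertex identities deranged as
planted ground truth, perturbed by edge permutation, vertex deletion,
or additive Gaussian edge noise, and scored by the mean normalized
rank of the planted changes (1 = all recovered at the bottom of the
list, 0.5 = chance).

## Worked example

Simulate paired transcriptome/proteome-style tables for two phenotypes
in which 10 designated genes rewire their co-expression partners
between sources, then run the differential integration:

```r
library(netconcord)

sim <- simulate_abundance_pair(n_genes = 60, n_changed = 10,
                               samples_per_phenotype = 20, seed = 42)
res <- differential_integrate(
  sim$tables, phenotypes = c("basal", "luminal"),
  mode = "local", method = "spearman", p_threshold = 0.05,
  bootstrap = bootstrap_config(n_resamples = 1000, seed = 42))
ranked <- rank_genes(res)
head(ranked, 5)
#> # A tibble: 5 × 6
#>   gene  score ci_low ci_high ci_width  rank
#>   <chr> <dbl>  <dbl>   <dbl>    <dbl> <int>
#> 1 g58   0.942  0.796   1.000    0.204     1
#> 2 g14   0.940  0.691   0.999    0.309     2
#> 3 g20   0.937  0.636   0.997    0.361     3
#> 4 g32   0.935  0.689   1.000    0.311     4
#> 5 g13   0.934  0.720   0.985    0.264     5

accuracy(ranked, sim$changed)
#> [1] 0.8633333
```

Genes at the top (scores near 1 with narrow CIs) have neighborhoods
conserved across the two sources; the planted rewired genes sink to
the bottom — their mean normalized rank 0.86 is far above the 0.5
chance level. The robustness benchmark summarizes recovery under
noise:

```r
bench <- run_benchmark(simulation_spec(
  n_vertices = 100, noise_kind = "gaussian", noise_levels = c(0, 6),
  mode = c("local", "global"), n_replicates = 10, seed = 1))
glance(bench)
#> # A tibble: 4 × 7
#>   kind     level n_networks mode   mean_accuracy sd_accuracy n_replicates
#>   <chr>    <dbl>      <dbl> <chr>          <dbl>       <dbl>        <int>
#> 1 gaussian     0          2 global         0.970     0.0147            10
#> 2 gaussian     0          2 local          0.975     0.00885           10
#> 3 gaussian     6          2 global         0.923     0.0594            10
#> 4 gaussian     6          2 local          0.481     0.0555            10
```

Global similarity barely notices even σ = 6 edge noise while local
similarity degrades with σ — the diffusion view of the neighborhood
averages the noise out. `autoplot()` methods draw the ranked list,
the benchmark curves, and clumpiness heatmaps; `tidy()`/`glance()`
give tabular views of networks and benchmark runs.

## Command line

A thin dispatcher over the same functions lives at
`inst/cli/netconcord` (installed under the package's `cli/`
directory):

```sh
netconcord build-net --abundance t.tsv --metadata m.tsv --method spearman --p-threshold 0.05 --out net.tsv
netconcord integrate --net-a a.tsv --net-b b.tsv --mode global --beta 0.4 --out scores.tsv
netconcord differential --abundance-a t.tsv --abundance-b p.tsv --metadata m.tsv \
    --phenotypes basal,luminal --mode local --out ranked.tsv
netconcord rankprod --lists r1.tsv,r2.tsv --n-perm 1000 --seed 1 --out agg.tsv
netconcord compare --results r1.tsv,r2.tsv,r3.tsv --newick tree.nwk --out rho.tsv
netconcord biomarkers --matrix cm.tsv --ci-max 0.04 --out calls.tsv
netconcord simulate --spec spec.yaml --out results.tsv
netconcord clumpiness --tree tree.nwk --labels labels.tsv --out clump.tsv
```

Every subcommand takes `--config file.yaml` for defaults; explicit
flags win. Logs (stage timings, gene/edge counts) go to stderr.

## Acceptance script

`scripts/acceptance.R` re-runs the package's headline robustness
measurement from scratch: it generates 100-vertex scale-free networks
with 5% planted vertex changes, sweeps Gaussian edge noise over
σ ∈ {0, 2, 4, 6} with 20 replicates each using global similarity, and
reports the worst per-σ mean recovery accuracy as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
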
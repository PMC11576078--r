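# metaSNF

Multi-omics molecular subtyping by **metagene similarity network
fusion**: each omics layer is first compressed into a few metagenes by
KL-divergence non-negative matrix factorization (rank chosen by
consensus-matrix cophenetic stability), per-layer patient similarity
networks built on those metagenes are fused by the SNF message-passing
iteration, and the fused network is partitioned by spectral clustering
with eigengap model selection. The package also ships the plain SNF
baseline, a synthetic multi-omics benchmark with planted subtypes,
clustering metrics (NMI, Davies–Bouldin, Calinski–Harabasz, Dunn), and
the preprocessing filters commonly applied to tumor expression and
methylation tables.

## The method in brief

For layers $A_m \in \mathbb{R}_{\ge 0}^{p_m \times n}$,
$m = 1,\dots,M$:

1. **Metagenes.** Minimize the generalized Kullback–Leibler divergence
   $\mathrm{KL}(A_m; W_m H_m) = \sum_{ij}(A_{ij}\log\frac{A_{ij}}{(WH)_{ij}} - A_{ij} + (WH)_{ij})$
   by multiplicative updates; pick the rank $k_m$ by the largest drop in
   the cophenetic correlation of consensus matrices over restarts. The
   metagene matrix $H_m$ ($k_m \times n$) goes downstream.
2. **Affinity.** $S_m(a,b) = \exp(-d^2(a,b) / (\mu\,\varepsilon_{a,b}))$
   with the locally adaptive scale
   $\varepsilon_{a,b} = (\bar d(a,N_a) + \bar d(b,N_b) + d(a,b))/3$
   averaged over each sample's $K$ nearest neighbors; $\mu = 0.5$,
   $K = 20$ by default.
3. **Fusion.** Iterate
   $P^{(m)} \leftarrow D^{(m)} \big(\sum_{f\ne m} P^{(f)}/(M{-}1)\big) (D^{(m)})^\top$
   for $T = 20$ rounds, where $P$ is the row-stochastic global kernel
   (diagonal 1/2) and $D$ the row-normalized $K$-nearest-neighbor
   carrier; average and symmetrize into the fused network $G$.
4. **Clustering.** Normalized spectral clustering on $G$; the number of
   subtypes is fixed by the user or chosen by the Laplacian eigengap.

## Worked example

Generate a synthetic 3-layer cohort whose four subtypes are only
identifiable by integrating all layers, then subtype it:

```r
library(metaSNF)

ds <- simulate_multiomics(sigma2 = 6, signal_prop = 0.2, seed = 1)
res <- run_meta_snf(ds$layers, ranks = 2:5, n_runs = 5,
                    max_iter = 600, tol = 1e-5, k = 4, seed = 1)

res$selected_ranks       # NMF rank chosen per layer
nmi(ds$true_labels, res$labels)
```

```
#> [1] 3 3 2
#> [1] 0.9822832
```

Two to three metagenes per layer and NMI ≈ 0.98 against the planted
subtypes at the low-noise setting — a near-perfect recovery. The plain
SNF baseline on the same data —

```r
base <- run_snf_baseline(ds$layers, k = 4, seed = 1)
nmi(ds$true_labels, base$labels)
```

```
#> [1] 0.5625662
```

— is noticeably weaker, which is the point of the metagene step.
`run_benchmark()` repeats this comparison over the full noise ×
signal-proportion grid, and `eigengap_k()` / `validity_indices()`
support cluster-number diagnostics and internal validity scoring. A
command-line front end for all steps is installed at
`inst/cli/meta_snf.R` (subcommands `simulate`, `run`, `snf-baseline`,
`benchmark`, `metrics`).

For real omics tables, condition each layer first:

```r
x <- read_omics_matrix("mrna.tsv")
x <- drop_high_missing(x, max_missing = 0.30)
x <- knn_impute(x, k = 10)
x <- log_transform(x)
x <- low_variation_filter(x, percentile = 0.15)
```

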
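# seomlr

One-step multi-view subspace clustering for multi-omics cancer subtyping.

`seomlr` partitions tumour samples from several omics views measured on the
same cohort — e.g. mRNA expression, miRNA expression and DNA methylation —
in a single joint optimization, for researchers who want an integrative
subtyping that also exploits the label sets other clustering tools produce.

## The model

Given views $X^{(v)} \in \mathbb{R}^{d_v \times n}$ and (optionally) base
clusterings encoded as indicator matrices $Y_p$, the method minimizes

$$
\sum_{v}\Big(\|E^{(v)}\|_1 + \xi_1\|Z^{(v)}\|_1
+ \xi_2\sum_{w\neq v}\|Z^{(v)}\odot Z^{(w)}\|_1\Big)
+ \mathrm{Tr}(F^{\top} L F) + \eta\|F - GR\|_F^2
$$

subject to $X^{(v)} = X^{(v)}Z^{(v)} + E^{(v)}$,
$\mathrm{diag}(Z^{(v)})=0$, $F \ge 0$, $F^{\top}F = I$, $R^{\top}R = I$ and
$G$ a hard cluster indicator, where
$L = \xi_3(\sum_v L^{(v)} + \delta\sum_p \beta_p L_p)$ combines the
Laplacians of the per-view self-representation graphs with co-membership
Laplacians of the base clusterings, self-weighted by
$\beta_p = 1/(2\,\mathrm{Tr}(F^{\top}L_pF))$ so better-agreeing base methods
contribute more without extra tuning. Sparse self-representations are solved
per view by ADMM; the discrete indicator comes from spectral rotation
($\min_{G,R}\|F-GR\|_F^2$) inside the same loop — no post-hoc k-means.

The package also ships base-clustering providers (similarity network fusion,
normalized-cuts spectral clustering, k-means), a synthetic multi-omics
generator with planted subtypes and graded extra noise, clustering-agreement
metrics (NMI, ARI), a replicate benchmark harness, and a command-line
interface (`inst/cli/seomlr`).

## A worked example

```r
library(seomlr)

# three views, 200 samples, 4 planted subtypes, 5% corrupted entries
sim <- simulate_multiomics(extra_noise = 0.05, seed = 1)

# base clusterings: SNF on all views + spectral clustering per single view
bases <- list(
  snf_fuse(sim$dataset, c = 4, seed = 11),
  spectral_cluster(sim$dataset$views$methylation, c = 4, seed = 12),
  spectral_cluster(sim$dataset$views$miRNA, c = 4, seed = 13))

fit <- seomlr(sim$dataset, c = 4, bases = bases, pca_components = 4, seed = 1)
fit
#> One-step multi-omics subspace clustering (seOMLR)
#>   200 samples, 3 view(s), 3 base clustering(s), c = 4 (one-step)
#>   outer iterations: 3 (co-clustering converged)
#>   cluster sizes: 50, 49, 50, 51

agreement_report(fit$labels, sim$truth)
#> clustering agreement: NMI = 0.9823, ARI = 0.9866

round(coef(fit) / sum(coef(fit)), 3)   # relative ensemble weights
#>      SNF spectral spectral
#>    0.804    0.061    0.135
```

Three outer iterations of the alternating loop suffice for the co-clustering
matrix to stop changing; the recovered partition misplaces one sample out of
200 (NMI 0.98), and the self-weighting assigns SNF — the most accurate base
clustering — 80% of the ensemble weight.

The fitted object carries the discrete indicator `G`, the continuous
embedding `F`, the per-view self-representations `Z`, the ensemble weights
(`coef(fit)` — here SNF dominates, as it should when it is the most accurate
base), the sparse residuals (`residuals(fit)`), and an objective trace
(`plot(fit)`). `seomlr_two_step()` fits the same model but discretizes `F`
with k-means, to quantify what the one-step rotation buys;
`run_noise_benchmark()` scores every method over seeded replicates at 0%,
5% and 15% extra noise.

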
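# ggmboot

Gaussian graphical models (GGMs) describe which variables in a
multivariate normal vector remain dependent after adjusting for all
the others: an edge between $Y_i$ and $Y_j$ means the partial
correlation

$$\rho_{ij} = -\frac{k_{ij}}{\sqrt{k_{ii} k_{jj}}}, \qquad K = \Sigma^{-1}$$

is non-zero.  The standard edge test — Fisher's Z transform
$R_{ij} = \tfrac12\log\frac{1+\hat\rho_{ij}}{1-\hat\rho_{ij}}$ referred
to its iid null $N(0, 1/(N-p-3))$ — assumes independent observations.
In family studies and other clustered designs observations within a
cluster are correlated, and the iid test inflates the type I error by
several fold as the within-cluster (genetic) correlation grows.

`ggmboot` learns GGMs from such data with a **cluster bootstrap** edge
test: whole clusters are resampled with replacement, the standardized
Fisher statistic $R^{*t} = \sqrt{N_t - p - 3}\,R^t$ is recomputed on
each resample, and

$$Z_{ij} = \frac{\sqrt{N - p - 3}\,R_{ij}}{\widehat{se}(R^*_{ij})}$$

replaces the analytic null standard deviation with the bootstrap one.
Only the cluster memberships are needed — no kinship model or
heritability estimate.  The package is aimed at statistical
geneticists and systems biologists working with family cohorts,
longitudinal panels, or any cluster-sampled multivariate data.

It also ships the baselines the method is judged against (the iid
Fisher test and a naive row-resampling bootstrap), a
variance-components simulator of multivariate family traits, and a
simulation harness for false-positive-rate and power studies.

## Worked example

```r
library(ggmboot)

# ground truth: chain graph 1 - 2 - 3, partial correlations 0.3;
# variables 1 and 3 are conditionally independent given 2
g <- canonical_graph("chain", strength = 0.3)

# 120 families (60 of size 3, 60 of size 7; N = 600), heritability 0.6
d <- simulate_traits(trait_model(g, heritability = 0.6),
                     build_families(120), seed = 7)

iid_edge_test(d)[, c("var_i", "var_j", "rho_hat", "Z", "p_value")]
#>   var_i var_j     rho_hat         Z      p_value
#> 1    V1    V2 0.342705525 8.7046201 3.186403e-18
#> 2    V1    V3 0.009456956 0.2304929 8.177088e-01
#> 3    V2    V3 0.255492774 6.3679568 1.915628e-10

res <- bootstrap_edge_test(d, bootstrap_config(T = 50, seed = 8))
res$edges[, c("var_i", "var_j", "rho_hat", "Z", "p_value")]
#>   var_i var_j     rho_hat         Z      p_value
#> 1    V1    V2 0.342705525 6.7165487 1.860791e-11
#> 2    V1    V3 0.009456956 0.1903903 8.490033e-01
#> 3    V2    V3 0.255492774 5.1896350 2.107067e-07
```

Point estimates are identical — clustering biases the *variance*, not
the partial correlations.  The cluster bootstrap's standard errors are
about 25–30% wider than the iid ones here (e.g. `Z` for the V1–V2 edge
drops from 8.70 to 6.72): that is the variance the iid test
understates at heritability 0.6, and across many datasets it is
exactly what turns into a 2–4-fold inflated false positive rate on
null pairs.  Both true edges stay decisively significant.
`learn_ggm()` returns just the rejected pairs as the learned graph,
with Bonferroni correction recommended for real data:

```r
learn_ggm(d, bootstrap_config(T = 50, seed = 8,
                              correction = "bonferroni"))$edges[, 1:2]
#>   var_i var_j
#> 1    V1    V2
#> 3    V2    V3
```

The same inference is available from a shell via the thin wrapper
`exec/ggmboot`:

```sh
Rscript exec/ggmboot infer --input data.tsv --cluster-col FAMID \
  --mode cluster --T 50 --c 100 --alpha 0.05 \
  --correction bonferroni --seed 17 --out edges.tsv
```

For study design, `scenario()` + `estimate_fpr()` /
`adjust_alpha()` + `estimate_power()` evaluate any (graph, family
count, heritability, method) cell, and `run_grid()` sweeps a whole
design from a YAML config.  See the vignette
(`vignettes/cluster-bootstrap-ggm.Rmd`) for the model, the algorithm,
and every numerical choice.

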
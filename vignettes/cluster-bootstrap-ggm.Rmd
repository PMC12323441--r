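---
title: "Learning partial correlation networks from clustered data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning partial correlation networks from clustered data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggmboot)
```

## The model

A Gaussian graphical model (GGM) represents the conditional
independence structure of a multivariate normal vector
$Y = (Y_1, \dots, Y_p)^T \sim MVN(\mu, \Sigma)$ by an undirected graph:
vertices are variables, and an edge $\{i, j\}$ is present exactly when
the partial correlation

$$\rho_{ij} = -\frac{k_{ij}}{\sqrt{k_{ii} k_{jj}}}, \qquad
  K = \Sigma^{-1},$$

is non-zero, i.e. when $Y_i$ and $Y_j$ remain dependent after adjusting
for all other variables.  `graph_from_partial_corr()` constructs a
ground-truth model from a partial correlation matrix $P$ by rebuilding
$K$ (unit diagonal, off-diagonal $-\rho_{ij}$) and $\Sigma = K^{-1}$;
`partial_corr_from_cov()` goes the other way for estimation, and its
output is checked in the test suite against an independent brute-force
oracle (correlation of regression residuals via Schur complements).

With $N$ iid observations, the classical edge test transforms the
estimated partial correlation with Fisher's variance-stabilizing
transform $R_{ij} = \tfrac12 \log\frac{1+\hat\rho_{ij}}{1-\hat\rho_{ij}}$,
whose null distribution is approximately $N(0, 1/(N - p - 3))$.
`iid_edge_test()` implements this test.  It is exact in its own terms
but silently assumes independent rows.

## Why clustered data break the iid test

Family studies (and clustered designs generally) violate row
independence.  We model a trait of individual $k$ in family $m$ as
$y_{mk} = \mu + e_{mk} + g_{mk}$ with independent environmental
components $e_{mk} \sim N(0, \sigma^2_e)$ and genetic components
$g_{mk} \sim N(0, \sigma^2_g)$ that are shared within families:
$\mathrm{cov}(y_{mk}, y_{mh}) = 2^{-d} \sigma^2_g$ for a $d$-th degree
relative pair.  Stacking $p$ traits, the multivariate form is

$$Y = \mu + E + G, \qquad
  E \sim MVN(0, I_N \otimes \Sigma_e), \quad
  G \sim MVN(0, \Phi \otimes \Sigma_g),$$

where $\Phi$ is the block-diagonal relatedness matrix
(`relatedness_matrix()`: entries $2^{-d}$, 1 on the diagonal, 0 across
families) and $\Sigma = \Sigma_e + \Sigma_g$ is the covariance whose
inverse defines the graph.  Heritability enters as a single scalar
$h^2$: $\Sigma_g = h^2 \Sigma$, $\Sigma_e = (1 - h^2)\Sigma$
(`trait_model()`).  A matrix-valued heritability is deliberately not
supported: with a non-diagonal heritability matrix the implied
covariance $(\Phi - I) \otimes H\Sigma + I \otimes \Sigma$ is not
guaranteed to be positive semi-definite.

Under this model each row is still marginally $MVN(\mu, \Sigma)$, so
the point estimate $\hat P$ is consistent — but the sampling variance
of $R_{ij}$ is larger than $1/(N - p - 3)$, increasingly so as $h^2$
grows.  Referring $R_{ij}$ to the iid null therefore inflates the type
I error; the simulation harness below measures 2–4-fold inflation for
the iid test once $h^2$ exceeds 0.5.

## The cluster bootstrap edge test

`bootstrap_edge_test()` keeps the Fisher statistic but replaces its
analytic null standard deviation with a cluster bootstrap estimate.
For $t = 1, \dots, T$:

1. draw $\mathrm{round}(cM/100)$ of the $M$ clusters with replacement
   and stack all rows of every drawn cluster (duplicates included);
   the resample size $N_t$ varies when cluster sizes differ;
2. compute the sample covariance $S_t$, the partial correlations
   $P_t = -D_t^{-1/2} S_t^{-1} D_t^{-1/2}$, the Fisher statistics
   $R^t_{ij}$, and $R^{*t}_{ij} = \sqrt{N_t - p - 3}\, R^t_{ij}$.

The standard error is the sample standard deviation of
$\{R^{*t}_{ij}\}_{t=1}^T$ (divisor $T - 1$), and the test statistic is

$$Z_{ij} = \frac{\sqrt{N - p - 3}\, R_{ij}}{\widehat{se}(R^*_{ij})},$$

with $R_{ij}$ from the **original** data — the bootstrap supplies only
the denominator, and no bias correction is applied.  $|Z_{ij}| >
z_{\alpha/2}$ rejects conditional independence (the two-sided reading
of the rejection rule, matching the two-sided alternative
$\rho_{ij} \neq 0$).  Resampling whole clusters preserves the
within-cluster dependence in every resample, which is what makes the
SE estimate honest; the `"individual"` mode (the naive bootstrap that
resamples rows) is provided as a baseline and inherits the iid test's
inflation.

Defaults are $T = 50$ and $c = 100$: in the simulation study 50 and
200 resamples with 100% of families drawn perform equally well, while
$c < 100$ costs power through the reduced resample size.  Multiple
testing: `correction = "bonferroni"` divides $\alpha$ by $p(p-1)/2$
and is the recommended setting for learning a real network
(`learn_ggm()`); simulation mode uses per-edge $\alpha$ so that
rejection rates are interpretable as per-edge FPR and power.

### Numerical choices and degenerate inputs

* The diagonal of $-D^{-1/2} S^{-1} D^{-1/2}$ is $-1$ identically; it
  is overridden to $+1$, the standard partial correlation convention.
  Only off-diagonal entries are tested.
* A covariance with reciprocal condition number below $10^{-12}$
  raises a "precision matrix not estimable" error; no ridge or
  shrinkage is applied anywhere.
* A resample with $N_t \le p + 3$, a singular $S_t$, or a partial
  correlation of magnitude 1 is redrawn (keeping the SE divisor
  $T - 1$ well defined); redraws are counted in the diagnostics and
  the test aborts if more than half of all draws are degenerate.
* If every resampled statistic is identical the SE is exactly 0; this
  is reported as a degeneracy error rather than an infinite $Z$.
* The sample covariance uses divisor $N - 1$; at the sample sizes of
  interest the distinction from $N$ is far below Monte Carlo
  resolution.
* All seeded entry points save and restore the caller's RNG state, and
  one master seed spawns independent substreams per replicate, so runs
  are bit-reproducible and replicates individually recomputable.

### What the finite-$T$ standard error costs

With $T = 50$, $\widehat{se}$ has about 49 degrees of freedom, and
referring $Z$ to $N(0, 1)$ instead of a $t$-distribution puts a floor
of roughly $P(|t_{49}| > 1.96) \approx 0.056$ under the null even with
a perfectly calibrated SE.  The acceptance tests measure the cluster
bootstrap's FPR at $M = 360$ at about 0.05–0.07 across heritabilities
— flat in $h^2$, unlike the iid test — and the test suite verifies the
bootstrap SE against the true sampling spread of $R^*$.  Users who
want the last half-point of calibration can raise `T` to 200 at linear
cost.

## The family simulator

`build_families(M)` reproduces the mixed design used throughout the
study: $M/2$ families of two parents and one offspring and $M/2$ of
two parents and five offspring, so $N = 5M$ (200, 600, 1800 for
$M = 40, 120, 360$).  `simulate_traits()` samples family blocks from
$\Phi_m \otimes \Sigma_g + I \otimes \Sigma_e$ (individual-major
ordering: individuals outer, traits inner — the trait-major stacking
above is the same distribution under a fixed permutation), batching
families that share a size through one Cholesky factor.  Spouses share
no environmental component beyond $\Sigma_e$'s independence — the
environmental term is independent for every individual, exactly as the
variance decomposition states.  Odd $M$ is rejected rather than split
arbitrarily.

The canonical ground-truth graphs are the independence graph (3
vertices, no edges), the chain ($1 - 2 - 3$, where $\rho_{13} = 0$ but
$\Sigma_{13} \neq 0$), the triangle-tail (triangle $1, 2, 3$ with 4
attached to 3 alone), and `prs_like`, a seeded sparse random network
standing in for a polygenic-risk-score panel, with edge magnitudes
bounded below at 0.01 and exact zeros elsewhere.  The edge strength
defaults to a partial correlation of 0.3 — the magnitude at which
power saturates above 0.8 in the study design — and is configurable;
the published figures of the three small graphs do not print their
numeric matrices, so these values are this package's own documented
choice, not reproduced constants.

What the simulator deliberately does **not** emulate: multi-generation
pedigrees, inbreeding, dominance or epistatic genetic models,
genetically correlated traits (non-scalar $H$), shared household
environment, and non-Gaussian (skewed or heavy-tailed) traits.
Passing tests therefore speak to additive, Gaussian, two-generation
family data; real data that depart from these assumptions — notably
skewness — are outside what the simulations validate.

## The simulation harness

`scenario()` fixes a (graph, $M$, $h^2$, method) cell;
`estimate_fpr()` and `estimate_power()` report per-pair rejection
proportions with binomial standard errors over replicate datasets.
Because inflated methods would win power comparisons unfairly,
`adjust_alpha()` rescales the operative level by the measured mean
inflation,

$$\alpha^* = \frac{0.05}{\overline{FPR} / \alpha},$$

with $\overline{FPR}$ the null-pair rejection rate averaged over pairs
and measured **at the current operative level** $\alpha$, iterating
with a fresh replicate stream each round until the empirical FPR is
within `tol` of nominal.  Read this way the update has the nominal FPR
as its fixed point; reading the denominator's $\alpha$ as the fixed
nominal level instead would converge to the wrong target whenever more
than one iteration is needed.  Exact equality of an empirical
proportion is unattainable, so stopping is tolerance-based
(`tol = 0.005` by default, which should not be set much below the
binomial Monte Carlo error $\sqrt{\alpha(1-\alpha)/\text{replicates}}$);
on hitting `max_iter` the level whose measured FPR came closest is
returned and flagged.  An estimated FPR of exactly 0 caps the level at
1 with a warning, since no finite inflation can be measured.

`run_grid()` sweeps graphs $\times$ $M$ $\times$ $h^2$ $\times$
methods, writing per-cell results incrementally and recording (rather
than propagating) cell failures.  Power for `prs_like` graphs can be
summarized by binning true edges by $|\rho|$ (0.1 / 0.2 / 0.3), since
power is driven by the partial correlation magnitude.

### Problem sizes

The package-default replicate count is 1000 per cell, matching the
design of the study.  The shipped acceptance checks run 300–1500
replicates per cell with 99% binomial bands at $M \le 360$, sizes
chosen so the full statistical validation completes in minutes on one
core while keeping Monte Carlo error small against each band; the
vignette and README examples use smaller $M$ still.  All of those are
choices of this package's own validation design, not of the method.

## Worked example

```{r example, eval = FALSE}
g <- canonical_graph("chain", strength = 0.3)
d <- simulate_traits(trait_model(g, heritability = 0.6),
                     build_families(120), seed = 7)

# conventional test vs cluster bootstrap
iid_edge_test(d)
bootstrap_edge_test(d, bootstrap_config(T = 50, seed = 8))

# the learned graph
learn_ggm(d, bootstrap_config(T = 50, seed = 8,
                              correction = "bonferroni"))$edges
```

A command-line wrapper, `exec/ggmboot`, exposes the same inference on
a delimited table (`ggmboot infer --input data.tsv --cluster-col FAMID
--out edges.tsv`).

## Known limitations

* The bootstrap SE is unreliable with few clusters: at $M = 40$ the
  FPR inflates by roughly 1.5-fold regardless of heritability (the
  harness reproduces this), and below that the test becomes liberal
  enough that results should not be trusted.
* $N \le p + 3$ leaves the statistic undefined; there is no sparse or
  penalized fallback, and graphical-lasso-style estimation is out of
  scope.
* FDR control is not implemented; the only multiplicity correction is
  Bonferroni.
* Heritability is a single scalar shared by all traits.
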
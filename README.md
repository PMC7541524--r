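# tradeflow

Longitudinal dyadic mixed-effects modelling and cluster analysis for
directed, weighted bilateral trade networks.

## The problem

Bilateral commodity trade (the motivating application is global meat
trade in tonnes, FAO-trade-matrix style data) forms a directed weighted
network per year: countries are nodes, the flow from sender *i* to
receiver *j* in year *t* is an edge weight *y<sub>ijt</sub>*. Two questions
recur in this literature:

1. **Structure** — which groups of countries trade preferentially with
   each other, and how do those clusters change over time?
2. **Drivers** — which political/economic/environmental factors explain
   flow volumes, once network dependence (country-level export/import
   propensities, within-pair reciprocity) and temporal dependence
   (persistence of those propensities across years) are accounted for?

`tradeflow` implements both halves as a tested, reusable pipeline, plus a
synthetic-data generator with known ground truth so every stage can be
validated without access to proprietary data.

## The model

The core is a longitudinal gravity model with latent sender/receiver and
reciprocity structure (a dynamic social-relations / latent-space model in
the Westveld–Hoff tradition). On the log scale, for ordered dyad (i, j)
in year t:

```
z_ijt = β_0t + β_1t Agreement_ijt + β_2t ln Dist_ij
      + β_3t ln GDPpc_it + β_4t ln GDPpc_jt + β_5t ln Pop_it + β_6t ln Pop_jt
      + β_7t ln Pasture_it + β_8t ln Pasture_jt + β_9t ln DES_it + β_10t ln DES_jt
      + s_it + r_jt + γ_ijt
```

with `z = ln(1 + y)` (zero flows stay in the data as exact zeros), and

* `(s_it, r_it)` — country i's latent export/import propensity, a
  stationary VAR(1): `u_it = Φ u_i,t−1 + ε_it`, `ε ~ N(0, Σ_ε)`. The
  diagonal of Φ (φ_s, φ_r) measures year-to-year persistence of export
  and import activity; the off-diagonals (φ_sr, φ_rs) are cross-effects.
* `(γ_ijt, γ_jit)` — the dyadic residual pair, correlated within a pair
  (reciprocity ρ), marginal variance σ²_γ, AR(1) over time with
  coefficient φ_gg.

Estimation is fully Bayesian via a Gibbs sampler with one Metropolis
block (`gibbs_fit()`); defaults mirror the standard practice of 11,000
iterations, 1,000 burn-in, thinning by 10. Coefficients are summarised by
posterior means with 95% highest-posterior-density intervals; temporal
parameters by medians with equal-tail 95% quantile intervals
(`summarize_posterior()`).

Per-year network structure comes from directed weighted modularity
(`directed_modularity()`, exact branch-and-bound optimisation at small n,
deterministic greedy agglomeration at scale, a walktrap-style random-walk
method, k-core decomposition, adjusted-Rand comparison). Robustness of a
fitted coefficient is quantified by the replacement-of-cases framework
(`rir()`, `rir_from_posterior()`): the fraction of cases that would have
to be replaced by zero-effect cases to invalidate the inference at
α = 0.05, using the time-series (autocorrelation-aware) standard error of
the MCMC chain.

## Worked example

```r
library(tradeflow)

cfg <- synthetic_config(n_countries = 20, n_years = 6, seed = 11,
                        phi_matrix = matrix(c(0.9, 0, 0, 0.8), 2, 2),
                        phi_gg = 0.3, rho = 0.5)
dat <- simulate_dataset(cfg)          # panels + tensor + latent truth
des <- build_design_matrices(dat$panel, dat$dyads, tensor = dat$tensor)
fit <- gibbs_fit(des, iterations = 1500, burn_in = 500, thin = 5, seed = 2)
summarize_posterior(fit)
```

```
<posterior_summary>

Temporal dependence (median [2.5%, 97.5%]):
 parameter  median   q2.5  q97.5
     phi_s  0.9006  0.819 0.9675
    phi_sr -0.0717 -0.245 0.0955
    phi_rs -0.0396 -0.144 0.0590
     phi_r  0.6898  0.481 0.8776
    phi_gg  0.3284  0.283 0.3663

43 of 66 coefficient-years significant at 95% HPD
```

The sampler recovers the generator's truth (φ_s = 0.9, φ_r = 0.8,
φ_gg = 0.3): the medians land on 0.90 / 0.69 / 0.33 with the truth inside
every interval. Cluster structure and robustness:

```r
cluster_years(dat$tensor, method = "greedy")$summary
#   year method n_clusters n_major modularity
# 1 1995 greedy          3       0 0.08935989
# 2 1996 greedy          3       1 0.21426753
# ...

rir_from_posterior(fit$beta[, "agreement", 6], df = 20*19 - 11,
                   n_cases = 20*19)
# <robustness_result> estimate 0.3135 (se 0.0088):
#   replace 94.5% of cases (359 of 380) to invalidate
```

i.e. 94.5% of dyad cases would have to be replaced with no-effect cases
to overturn the positive trade-agreement coefficient in the final year.

The one-call pipeline (`run_yearly_analysis(run_config(...))`) chains
simulate/load → filter → design → fit → cluster → robustness and returns
all report tables; a command-line front end is installed at
`inst/cli/tradeflow.R`.

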
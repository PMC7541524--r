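---
title: "Modelling longitudinal trade networks with tradeflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal trade networks with tradeflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`tradeflow` analyses panels of directed weighted networks — bilateral
trade quantities $y_{ijt}$ (tonnes) between $N$ countries over $T$ years —
in two complementary ways: community structure of each yearly network, and
a Bayesian longitudinal mixed-effects dyadic regression that explains flow
volumes while modelling network and temporal dependence. A synthetic-data
generator with known parameters makes the whole pipeline testable.

# The model and its assumptions

On the log scale the flow from sender $i$ to receiver $j$ in year $t$ is

$$z_{ijt} = x_{ijt}'\beta_t + s_{it} + r_{jt} + \gamma_{ijt},
\qquad z = \ln(1+y),$$

with an 11-column gravity design $x_{ijt}$: intercept; a 0/1
trade-agreement indicator (deliberately untransformed); and natural logs
of centroid great-circle distance, sender and receiver per-capita GDP,
population, pasture area, and dietary-energy-supply adequacy.

Latent structure:

* **Sender/receiver effects.** $u_{it} = (s_{it}, r_{it})'$ follows a
  stationary VAR(1), $u_{it} = \Phi u_{i,t-1} + \epsilon_{it}$,
  $\epsilon \sim N(0, \Sigma_\epsilon)$, with $u_{i1}$ drawn from the
  stationary law (the discrete-Lyapunov solution), so simulated and
  fitted series are stationary from the first year. $\Phi$'s diagonal
  ($\phi_s$, $\phi_r$) measures persistence of export/import propensity;
  off-diagonals are cross-lagged effects.
* **Dyadic residuals with reciprocity.** For each unordered pair the
  vector $(\gamma_{ijt}, \gamma_{jit})$ has marginal variance
  $\sigma^2_\gamma$, within-pair correlation $\rho$, and AR(1) temporal
  dependence with coefficient $\phi_{gg}$; the innovation covariance is
  scaled by $1-\phi_{gg}^2$ so the marginal law is time-invariant. The
  full covariance of a pair's $2T$ residuals is the Kronecker product
  $\Sigma_\gamma \otimes C_T$, $C_T[t,t'] = \phi_{gg}^{|t-t'|}$.

Assumptions worth stating: flows are conditionally log-normal given the
latent structure (no zero-inflation component — zeros enter as exact
zeros of $z$); covariate effects are linear on log scales and independent
across years a priori; dyad pairs are exchangeable given covariates.

## The zero-flow transform

Zero-filled trade matrices contain genuine zeros, on which $\ln y$ is
undefined. The package uses $z = \ln(1+y)$ with inverse
$y = \max(e^z - 1, 0)$ throughout (simulation floors negative latent
flows at zero). This is standard gravity-model practice; it compresses
nothing above a few tonnes ($\ln(1+y)\approx\ln y$) while keeping zeros
in the likelihood. Under the generator defaults the mean of $z$ is
around 7, so the flooring censors well under 5% of dyad-years; heavy
censoring (an intercept near 0) would bias variance parameters downward,
which is a limitation of the transform, not of the sampler.

# Estimation

`gibbs_fit()` is a Gibbs sampler with one Metropolis block. Per
iteration:

1. **Coefficients.** All $\beta_t$ are drawn jointly as a single
   conjugate multivariate normal of dimension $11T$ under the full dyadic
   error structure. (A per-year scan of the conditionals targets the same
   Gaussian; the joint draw is exact and mixes strictly better. The
   tridiagonal inverse of $C_T$ makes the precision block-tridiagonal in
   years, and its blocks reduce to fixed cross-products of the design —
   precomputed once — times scalars.)
2. **Latent trajectories.** Each country's $2T$-vector
   $(s_{i1},r_{i1},\dots,s_{iT},r_{iT})$ is drawn from the exact
   conditional: VAR(1) prior precision (block tridiagonal, stationary
   initial condition) plus $(N-1)$ copies of the dyadic residual
   precision $C_T^{-1}\otimes\Sigma_\gamma^{-1}$. Countries are scanned
   sequentially with running sums updated, which keeps the scan a valid
   Gibbs sweep at $O(NT)$ per country plus one $2T$ Cholesky per
   iteration.
3. **Residual structure.** $(\phi_{gg}, \rho, \log\sigma^2_\gamma)$ by a
   3-dimensional random-walk Metropolis step on the marginal likelihood
   of the dyad residual pairs, evaluated in $O(n_{pairs}T)$ through the
   AR(1) factorisation of $C_T^{-1}$ (the Kronecker form is verified
   against a dense-covariance oracle in the tests). Proposals outside
   $(-1,1)^2$ are rejected; step sizes adapt toward 30% acceptance during
   burn-in only and are frozen afterwards.
4. **Transition matrix.** $\Phi$ by a conjugate matrix-regression draw
   from the lag-1 regression of $u_{it}$ on $u_{i,t-1}$ (conditional
   likelihood, i.e. the $t=1$ stationary marginal is not differentiated
   through), rejected while the spectral radius is $\ge 1$.
5. **Innovations.** $\Sigma_\epsilon$ by a conjugate inverse-Wishart
   draw on the VAR innovations.

## Priors (all tunable via `priors =`)

| parameter | prior | default rationale |
|---|---|---|
| $\beta_t$ | $N(0, 100^2 I)$, independent per year | effectively flat on log scales |
| $\Sigma_\epsilon$ | Inv-Wishart$(4, I_2)$ | weakly informative, proper |
| $\sigma^2_\gamma$ | Inv-Gamma$(2, 1)$ | mean 1, infinite-variance tail |
| $\rho$, $\phi_{gg}$ | Uniform$(-1, 1)$ | support = validity region |
| $\Phi$ entries | $N(0,1)$ truncated to stationarity | keeps every draw a valid VAR |

$\beta_t$ are a priori independent across years: the per-year coefficient
trajectories are a reporting target, and no temporal prior linkage is
imposed on them. Chain defaults are 11,000 iterations, 1,000 burn-in,
thin 10; tests and the examples use reduced settings (hundreds to a few
thousand iterations), which parameter-recovery tests show is ample at
$N\le30$.

## Summaries

Two deliberately different summary styles: regression coefficients get
posterior mean + 95% **HPD** interval (narrowest window containing 95% of
sorted draws, oracle-tested against exhaustive search) with a
significance flag "HPD excludes zero"; temporal-dependence parameters get
median + equal-tail 2.5%/97.5% quantiles. Sender/receiver effects are
reported as per-country-year posterior means and their time averages
(which of the two a ranking should use is genuinely open; both are
returned).

`time_series_se()` implements the spectral-density-at-zero estimator via
an AIC-selected AR fit, the standard correction for MCMC autocorrelation;
it feeds the robustness analysis.

# Community structure

Yearly networks are scored with directed weighted modularity
$Q = \tfrac1w\sum_{c_i=c_j}(w_{ij} - w_i^{out}w_j^{in}/w)$. Three
optimisers:

* `exact_modularity_partition()` — branch-and-bound over restricted-growth
  assignments, exact up to a configurable node limit (default 16); the
  admissible bound adds every undecided pair's positive gain. Ties break
  to fewest clusters, then lexicographic labels.
* `greedy_modularity_partition()` — deterministic agglomeration by best
  positive merge gain (ties to the smallest label pair); the scalable
  stand-in, oracle-bounded by the exact result in tests.
* `walktrap_partition()` — random-walk profile distances at a
  configurable step count (default 4) on **symmetrized** weights (random
  walks on raw directed trade graphs can be absorbing), Ward
  agglomeration, and a dendrogram cut chosen by maximising the
  *directed* modularity of the original graph.

Partition agreement uses the adjusted Rand index; the comparison metric
and the walk length are package choices where the methodology literature
offers several equally defensible options. `k_core_levels()` peels the
binarized graph by total degree. "Major" clusters default to >10
countries.

# The synthetic generator: what it does and does not emulate

`synthetic_config()` states the simulated world once:

* Covariates are log-uniform within ranges chosen to span real-world
  orders of magnitude (GDP per capita 500–60,000 USD; population 0.1M–1.4B
  persons, stored in thousands; pasture 100–10⁶ km²; dietary-energy
  adequacy 85–140%); centroids are uniform over habitable latitudes;
  agreements are symmetric i.i.d. Bernoulli(0.3) per dyad-year.
* Default coefficients (`beta`) give $E[z]\approx7$ (≈1,000 t flows) so
  zero-flooring is a small tail; variance defaults
  ($\Sigma_\epsilon = 0.25I$, $\sigma^2_\gamma = 1$) put country effects
  and dyadic noise on comparable scales, and the default temporal
  parameters ($\phi_s=0.9$, $\phi_r=0.8$, $\phi_{gg}=0.3$, $\rho=0.5$)
  sit in the empirically plausible high-persistence / modest-reciprocity
  regime.

It does **not** emulate heavy-tailed country-size distributions,
geographic trade-bloc structure, commodity-level disaggregation, or
reporting error between exporter and importer records. A green
parameter-recovery test therefore establishes correctness of the sampler
under the model, not realism of the model for any particular dataset.

# Numerical choices and degenerate inputs

* Stationarity is enforced everywhere: config validation rejects
  non-stationary $\Phi$ and out-of-range $\phi_{gg}, \rho$; every saved
  MCMC draw satisfies the same invariants.
* $T = 1$ inputs are refused (the temporal model is undefined);
  $N \ge 3$ is required for the dyadic blocks to be informative.
* Rank-deficient designs abort before sampling, naming the collinear
  columns.
* Zero pasture area is floored at 1 km² before logging; zero-weight
  graphs are a modularity error; empty merge inputs are allowed and give
  empty output.
* Country filtering (missing covariates, then any zero-trade year) is
  iterated to a fixed point — the only order-independent reading of the
  two exclusion rules — and is idempotent by construction.
* Exporter-reported flows always take precedence over importer-reported
  flows; importer records are assumed reporter = importer and flipped.
  CSV round-trips print 17 significant digits so quantities survive
  write→read bit-exactly.

# Known limitations

* No zero-inflation/hurdle component: heavily censored panels (many true
  zeros) will bias $\sigma^2_\gamma$ and the intercept.
* Single-chain inference; convergence diagnostics are limited to the
  time-series SE (no R-hat across chains).
* The walktrap variant is a faithful-in-spirit re-implementation (profile
  distances + Ward + modularity cut), not a line-by-line port of any
  published code; it is validated on separable fixtures, not guaranteed
  optimal.
* Dyadic residual draws are stored only on request (`save_gamma`), since
  at full scale they dominate memory; they are reconstructable as
  residuals of the stored draws.
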
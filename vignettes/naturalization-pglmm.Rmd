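---
title: "Diversification rates and plant naturalization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversification rates and plant naturalization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Some angiosperm families contribute far more naturalized alien species to
the global flora than others. `natdiv` implements a family-level analysis
of that variation: does a family's macroevolutionary tempo — its net
diversification rate — predict its naturalization success, once propagule
pressure (horticultural use) and native range size are controlled for? The
unit of analysis is the plant family; families are phylogenetically
related, so the regression is a phylogenetic generalized linear mixed model
(PGLMM) with the family tree supplying the random-effect covariance.

## Variables

Every predictor and the response are built from species-level tables by
`build_family_dataset()`, applying the inclusion filter (at least 50
accepted species, a tip in the dated tree with a stem age, at least one
species with native range data):

* **Net diversification rate** (`stem_diversification_rate`). The
  method-of-moments estimator for stem clades,
  $r = \log(n(1-\varepsilon)+\varepsilon)/t$, with $n$ the extant accepted
  richness, $t$ the family stem age (Myr) and $\varepsilon = \mu/\lambda$
  the assumed relative extinction. Rates are computed at both bounds
  $\varepsilon = 0$ and $\varepsilon = 0.9$; the analysis uses the
  high-extinction value by default (`epsilon = 0.9`), with the
  $\varepsilon = 0$ column always reported alongside so their agreement can
  be checked on any data set.
* **Range sizes**. A species' range is the cumulative area (km²) of its
  occupied region polygons; regions carry a precomputed tropical/temperate
  area split, and the zonal ranges sum exactly to the total by
  construction. The family value is the mean over species with at least one
  native record — species with no distribution data are excluded from the
  mean rather than zero-filled, since a missing distribution is not a zero
  range.
* **Horticultural use**: the proportion of the family's accepted species in
  cultivation.
* **Naturalization success** (response): the proportion of the family's
  species naturalized anywhere, multiplied by the family's total count of
  naturalized (species, region) records. The region records are summed over
  species and *not* deduplicated across species: a region colonized by
  three species counts three times, which reads the index as "how many
  species escaped × how widely".

## Transforms and standardization

Area variables span orders of magnitude and are `log10(x+1)`-transformed;
the horticultural proportion and the response are right-skewed and
square-root transformed; the diversification rate is left untouched. After
transformation, main-effect predictors are standardized to mean 0, SD 1
(sample SD, $n-1$). Interaction columns are products of the standardized
parents and are *not* re-standardized, so main effects remain interpretable
at the interaction's zero point. The response is transformed but not
standardized by default. All of these maps are configurable per column
(`default_transforms()`, the `transforms` field of a model spec).

Three models are predefined (`model_spec()`): model 1 with diversification
rate, mean range and horticultural use; model 2 adds the tropical/temperate
range split and rate × range-zone interactions; model 3 instead adds a
rate × horticulture interaction. Diversification rate is present in every
model, including every candidate in stepwise selection.

## The model and the sampler

The fitted model is Gaussian:
$$y = X\beta + u + e, \qquad u \sim N(0, \sigma^2_p A), \qquad
  e \sim N(0, \sigma^2_e I)$$
where $A$ is the phylogenetic correlation matrix: shared root-to-MRCA path
length between two families, rescaled entrywise by
$1/\sqrt{A_{ii}A_{jj}}$ to unit diagonal. Rescaling to correlation form
makes $\sigma^2_p$ comparable across trees and is the common convention for
the animal model; non-ultrametric trees are accepted, the rescaling
handling unequal depths. When a tree is pruned to the analysis families,
the path between the original root and the MRCA of the retained set is kept
as a root edge, so pruning commutes exactly with taking a submatrix of the
correlation matrix.

Priors follow the weak inverse-Wishart convention: each variance component
gets a scalar inverse-Wishart(V = 1, nu = 0.002), i.e. inverse-gamma
(nu/2, nu·V/2); fixed effects get an effectively flat
Normal(0, $10^{10}$) prior.

`gibbs_fit()` samples the posterior with a blocked Gibbs sweep performed in
the eigenbasis of $A$ (one symmetric eigendecomposition per fit). Writing
$A = Q\Lambda Q'$ and rotating $y$ and $X$ by $Q'$:

1. $\beta$ is drawn from its conditional with $u$ integrated out — the
   marginal covariance is diagonal, $d_i = \sigma^2_p\lambda_i +
   \sigma^2_e$ — and then $u \mid \beta$ componentwise. Together this is an
   exact joint Gaussian draw of $(\beta, u)$, equivalent to the
   mixed-model-equations block but $O(np^2)$ per sweep instead of
   $O((n+p)^3)$.
2. $\sigma^2_p \sim \mathrm{IG}\big((\nu+q)/2, (\nu V + u'A^{-1}u)/2\big)$
   and $\sigma^2_e \sim \mathrm{IG}\big((\nu+n)/2, (\nu V + e'e)/2\big)$,
   with $u'A^{-1}u = \sum_i \tilde u_i^2/\lambda_i$ diagonal in the
   eigenbasis.

Eigenvalues of $A$ below $10^{-8}$ are lifted to $10^{-8}$ (a logged
diagonal jitter). For the order-level validation GLMM (`glmm_fit`) the
random-effect structure is the rank-deficient group matrix $ZZ'$; there the
zero eigen-directions are instead pinned at zero and the group quadratic
form is recovered through the pseudo-inverse, which reproduces
$u'u$ over the $q$ order effects exactly. The inner loop is compiled
(RcppArmadillo), as is usual for animal-model samplers.

The deviance $-2\log N(y \mid X\beta + u, \sigma^2_e I)$ is recorded at
every retained draw; `dic()` computes DIC $= \bar D + p_D$ with the plug-in
$p_D = \bar D - D(\bar\theta)$ at the posterior means of
$(\beta, u, \sigma^2_e)$ (the Spiegelhalter form).

### Chains, initialization, convergence

The full protocol is 520 000 iterations, burn-in 20 000, thinning 100,
three chains — 5000 retained draws per chain. Chains are overdispersed by
scaling the initial variances by 0.1/1/10 across chains, with $\beta$
started at the least-squares solution; each chain has its own seed
(`seed + chain - 1`) and identical seeds give bit-identical chains.
Convergence is declared when the Brooks–Gelman multivariate PSRF is below
1.1 (`gelman_rubin()`); the univariate factors use the standard
$\widehat{R}^2 = (n-1)/n + \frac{m+1}{mn}B/W$ form, which the test suite
cross-checks against `coda`. Effective sample sizes use the
spectral-density-at-zero estimate from an AIC-selected AR fit, summed over
chains and capped at the total retained count. `pMCMC` is
$2\min(\Pr(\theta>0), \Pr(\theta<0))$ floored at $2/N$ over the pooled
draws; at the full protocol's $N = 15\,000$ the floor is ≈ 0.00013 and is
formatted "< 0.0002".

Model-selection runs (`stepwise_selection`, every predictor subset always
containing the diversification rate, ranked by ascending DIC) default to a
reduced protocol — 52 000 / 2000 / 10, the same 5000 retained draws per
chain — because full-length chains for every subset are wasteful; winners
can be refit at full settings. The same reduced protocol is what the
bundled analysis scripts and the acceptance checks use throughout, and
chain-length doubling experiments in the test suite confirm posterior means
move by less than the Monte-Carlo error band.

## The synthetic-data generator

`simulate_study()` generates every input the pipeline consumes, with known
ground truth, so the whole chain — filtering, metric construction, design
assembly, sampling, diagnostics, selection — is testable without any
download:

* **Tree**: a birth–death tree conditioned on `n_families` extant tips
  (`ape::rphylo`; branch lengths in Myr; defaults birth 0.08, death 0.04).
  It is the reconstructed tree of survivors — extinct side branches are
  irrelevant because only extant families' stem ages feed the estimator.
* **Regions**: log-normal areas (meanlog 11 ≈ 6×10⁴ km² median, sdlog 1.3)
  with Beta(0.8, 0.8) tropical fractions, so regions tend to be
  predominantly tropical or predominantly temperate.
* **Richness**: log-normal (meanlog log 250, sdlog 1.2, capped at 5000),
  with 10% of families forced below 50 species to exercise the inclusion
  filter; with 200 candidate families ≈ 160 pass, the scale of the real
  168-family analysis. The family's true net rate is defined as
  $r_{\mathrm{true}} = \log(n)/t$, so the $\varepsilon = 0$ estimator
  recovers it exactly on the generated data.
* **Occupancy, horticulture**: each family gets a tropical-affinity weight
  and a 30-region pool; species occupy 1 + Poisson(2) pool regions.
  Horticulture flags are Bernoulli with family-level Beta(1.2, 2.8)
  propensities (≈ 30% base rate).
* **Response (inverse construction)**: for filter-passing families the
  latent score on the √ scale is $s = \mu_0 + x'\beta + u + e$ with
  standardized predictors, Brownian tip effects
  $u \sim N(0, \sigma^2_p A)$, and $e \sim N(0, \sigma^2_e I)$; defaults
  $\beta = (0.5, 0.4, 0.38)$ on (rate, mean range, horticulture),
  $\sigma^2_p = \sigma^2_e = 1$ — effect magnitudes of the size the
  family-level literature reports. $\mu_0 = 4$ keeps negative latents rare
  (< 1%); the few that occur have their residual redrawn (up to a capped
  number of rounds). Counts are then realized as
  $n_{\mathrm{nat}} = \mathrm{round}(\sqrt{s^2 n})$ clamped to
  $[1, n]$ and region records $= \max(n_{\mathrm{nat}},
  \mathrm{round}(s^2 n / n_{\mathrm{nat}}))$, so the recomputed index
  satisfies $\sqrt{(n_{\mathrm{nat}}/n) \cdot \mathrm{records}} = s$ up to
  integer rounding — relative error $O(1/\sqrt{s^2 n})$, in practice a
  worst-case absolute error ≈ 0.15 on the √ scale and far below the
  residual SD, and exactly 0 discrepancy on all counts when the pipeline
  recomputes the table.

All component seeds derive from one master seed by hashing the component
name (`component_seed`), so each piece is independently reproducible.

What the generator does *not* emulate: spatial autocorrelation and
dispersal limitation (regions are exchangeable given the family pool),
recording bias between regions, taxonomic error, non-Gaussian response
noise, and trait evolution beyond the Brownian tip effects. Passing tests
therefore demonstrate that the machinery is correct and calibrated under
the model's own assumptions — not that the Gaussian PGLMM is adequate for
any particular real data set.

## Numerical choices and degenerate inputs

* Eigenvalue floor $10^{-8}$ on $A$ (jitter, logged); non-PSD input beyond
  $-10^{-8}$ is an error.
* `standardize()` refuses constant vectors; `sqrt`/`log10p` refuse negative
  input, listing the offending rows.
* Missing branch lengths in a Newick string are an explicit error, never a
  silent default; malformed strings report a character offset.
* Degenerate Beta parameters (shape 0) in `simulate_regions` mean "fully
  temperate/tropical world" instead of NaN.
* HPD intervals are the shortest window containing 95% of sorted draws;
  quantile intervals can be obtained from the pooled draws directly.
* The manifest hash is a small polynomial rolling hash — a content
  fingerprint for reproducibility bookkeeping, not a cryptographic digest.

## Problem sizes used by the bundled checks

The analysis scripts and acceptance checks run the generator at its default
200 families / 150 regions (≈ 90 000 species) and fit with the reduced
chain protocol; sampler calibration uses 168-tip replicates (200 in the
test suite, 40 in the acceptance script) with one chain each. These sizes
were chosen so the whole workflow re-runs from scratch in minutes on one
core while keeping every check's Monte-Carlo error well inside its
assertion band.

## Known limitations

* Gaussian response only; proportions-times-counts responses with many
  zeros would need a hurdle or Poisson variant.
* DIC with the conditional (u-level) deviance penalizes the random effect
  heavily and is unstable when $A = I$ makes $(u, e)$ unidentifiable; use
  a structured $A$, as the analysis always does.
* The estimator treats richness and stem age as known; uncertainty in
  either propagates nowhere.
* Only exact label matching links families across tables and tree; no
  fuzzy taxonomy reconciliation.
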
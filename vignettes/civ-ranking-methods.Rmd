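---
title: "Ranking treatments with clinically important values: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking treatments with clinically important values: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(civrank)
```

## The model

`civrank` operates downstream of a network meta-analysis: its input is
the NMA's summary layer, a vector of relative effects of `I` treatments
versus a reference together with the covariance of those estimates (or,
equivalently, a league table of all pairwise contrasts with standard
errors). The working assumption throughout is the one under which those
summaries were produced: each relative effect is normally distributed,
`μ_i ~ N(μ̂_i, s_i²)`, and any pairwise contrast `μ_i − μ_j` is normal
with standard error `s_ij = sqrt(σ_ii + σ_jj − 2σ_ij)`.

Under that assumption the extent of certainty that treatment `i` beats
`j` by more than a clinically important value (CIV) is
`Φ((μ̂_i − μ̂_j − CIV)/s_ij)`, and the (CIV-conditioned) P-score of `i`
is the equal-weight average of these probabilities over its `I − 1`
competitors. Three exact identities anchor the implementation and are
enforced by the test suite:

* at CIV = 0 the pairwise probabilities for `(i, j)` and `(j, i)` sum to
  one, so the P-scores average exactly 0.5 over treatments;
* SUCRA computed from exact rank probabilities equals the P-score, and
  the simulated SUCRA converges to it at the Monte-Carlo rate
  `sqrt(0.25/n)`;
* SUCRA is an affine function of the mean rank,
  `SUCRA_i = (I − E[rank_i])/(I − 1)`.

For `K` outcomes the pairwise term generalizes to the orthant
probability of a standard `K`-variate normal whose k-th coordinate
bound is `(d_ij^(k) − c_k)/s_ij^(k)` and whose correlation is the
assumed between-outcome correlation matrix `ρ`, applied uniformly to
every treatment pair — the metric's formula admits no pair-specific
correlation. The joint probability can never exceed any marginal, it
factorizes at `ρ = 0`, and it collapses to the smaller marginal for
comonotone identical outcomes; all three behaviours are tested against
a brute-force sampling oracle.

A note on what `ρ` is: the quantity the joint metric needs is the
correlation of the *summary contrasts* across outcomes. It is commonly
discussed under the label "between-study correlation", and estimates
are rarely available because multivariate NMA is hard to fit; the
package therefore exposes the three pragmatic strategies —
independence, a fixed expert-informed matrix, or a sensitivity range —
via `correlation_strategy()`, and treats `ρ` as an assumption to be
varied, not a parameter to be estimated.

## Orientation and the CIV sign convention

Outcomes arrive in mixed directions (efficacy: larger better; weight
gain: smaller better). `orient()` negates the effects of `lower_better`
outcomes once at load, so every downstream formula can assume larger =
better; the covariance is unchanged because contrast variances are
invariant under a global sign flip. Double orientation is a guarded
error rather than a silent no-op.

All CIVs are then interpreted on the oriented *preference* scale:

* `civ > 0` demands a clinically important advantage of that size
  before a win counts;
* `civ < 0` tolerates a bounded disadvantage — the natural encoding for
  harm tolerances, where a grid running from 0 down to −1 SMD units
  asks "how does the hierarchy change as I accept up to one standard
  deviation more harm?".

This single convention was chosen over a re-signing rule tied to the
published direction because it is the only one under which both kinds
of sweep behave as described: every P-score curve is non-increasing in
the CIV, and deepening a harm tolerance (more negative CIV on the harm
outcome) can only *raise* a joint P-score — which is exactly how a
harmful-but-effective treatment climbs back up the hierarchy as
stakeholders accept more of its harm. A re-signing rule would make the
same grid a demanded margin on the harm outcome and invert that
behaviour.

## Parameters that matter

* **CIV grids** (`civ_spec`): units are those of the common effect
  scale (SMD after conversion). Default step 0.05 — crossings of
  P-score curves are typically reported at that granularity, and the
  linear interpolation used by `find_crossings()` is accurate to well
  under a step for the smooth curves Φ produces. Halving the step moves
  interpolated crossings by less than one original step (tested).
* **`n_samples`** for `simulate_ranks()`: default 1e5, giving ~0.0016
  Monte-Carlo error on any single rank probability. A seed is a
  required argument; the caller's RNG state is saved and restored, so
  ranking runs are reproducible without side effects.
* **Effect measure**: binary outcomes summarized as log odds ratios are
  rescaled to SMD by `√3/π` (the logistic-to-normal standard deviation
  ratio) at load. The conversion is linear, so the same factor applies
  to standard errors and its square to covariances. We rescale the
  covariance as well as the point estimates before any joint analysis —
  a stated assumption, since only the point conversion is standard.
* **Multivariate normal CDF**: deterministic TVPACK quadrature for
  nonsingular 2–3 outcome problems (absolute tolerance 1e-8);
  quasi-Monte-Carlo (Genz–Bretz) under a locally fixed RNG state for
  singular correlations or 4–6 outcomes, so repeated calls are
  bit-identical. More than 6 outcomes is refused: the joint orthant
  probability becomes so small that ranking on it is not meaningful in
  practice, and accuracy degrades.

## Numerical choices and degenerate inputs

* League-table reconstruction: `σ_ii = s_iR²`,
  `σ_ij = (σ_ii + σ_jj − s_ij²)/2`. Published league tables are rounded,
  so the reconstructed matrix can be slightly indefinite; eigenvalues
  down to `−1e-8 · λ_max` are clipped to zero, anything worse is an
  error reporting the smallest eigenvalue. The input pairwise standard
  errors are kept verbatim and used for all analytic P-scores, so
  clipping only affects the simulation path.
* The reference treatment is an ordinary member of the ranking with
  effect 0 and an exactly zero covariance row/column; the simulation
  path therefore always faces a singular covariance and uses an
  eigendecomposition sampler (`MASS::mvrnorm`) rather than a Cholesky
  factor.
* Ties in simulated ranks occur with probability zero for
  non-degenerate covariances; exact ties (degenerate σ) are broken
  uniformly at random from the run's seeded generator, which keeps the
  tallied rank matrix doubly stochastic in expectation.
* Curve crossings are sign changes of a score difference between
  adjacent grid points, located by linear interpolation; a curve pair
  that touches a common value at a grid point without changing order is
  deliberately not reported.
* P-score ties in rank tables are broken alphabetically and flagged in
  a `tied` column rather than silently ordered.

## The synthetic-network generator

No suitable public dataset ships with the package, so
`generate_network()` emulates the summary output of per-outcome NMA
models with known ground truth. True effects are uniform on
`[−0.6, 0.6]` SMD and basic-parameter standard errors uniform on
`[0.05, 0.3]` — the dynamic range seen in large psychiatric drug
networks, chosen once so synthetic P-score curves exhibit realistic
curvature. The covariance is a star (independent basic parameters)
plus a small shared rank-one loading, which is always positive
definite and gives mild off-diagonal covariance; estimates are the
truth plus one multivariate-normal noise draw coupled across outcomes
through `ρ`. Sizes used by the shipped tests and acceptance script
(networks of 2–16 treatments, 1e5 simulation draws, 1e5–1e6 oracle
samples) were picked to keep Monte-Carlo error well below the asserted
tolerances.

What the generator does *not* emulate — and therefore what passing
tests do not establish about real data: heterogeneity and
inconsistency of the underlying trial network, non-normal summary
distributions, selective reporting, and correlation structures richer
than a single exchangeable `ρ` between outcomes. The generator
validates the ranking layer's mathematics, not the NMA that feeds it.

## Known limitations

* The NMA itself is out of scope: effects, covariances and any
  within/between-study correlation must be estimated elsewhere.
* The joint metric assumes one correlation matrix for all treatment
  pairs, inherits all limitations of the normal approximation, and
  says nothing about which outcome drove a low joint score — users
  should always read it next to the per-outcome scores
  (`table1_style_report()` lays them side by side).
* CIVs are treated as known constants; eliciting them, and mapping
  them across effect measures, is a separate problem.
* Confidence intervals for SUCRA/P-scores are not provided; the
  metrics summarize estimation uncertainty, they do not carry their
  own.
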
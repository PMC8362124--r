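---
title: "Context-dependent species associations along a water-deficit gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent species associations along a water-deficit gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdjsdm)
```

## The scientific question

The stress-gradient hypothesis (SGH) predicts that facilitative
interactions among plants become more frequent as abiotic stress
increases. At continental scale, interactions are not observable
directly; what co-occurrence data offer instead are *residual
associations* — correlations between species' occurrences left over
after the measured environment has been accounted for. `cdjsdm` fits a
joint species distribution model (JSDM) in which those residual
associations are themselves functions of a stress covariate, the
growing-season climatic water deficit (CWD, in mm), so that one can ask
whether associations of drought-sensitive species become more positive
toward the dry end of the gradient.

## The model

Occurrence of species $j$ in plot $i$ is a probit regression on a latent
score,

$$y_{ij} = \mathbf{1}(z_{ij} > 0), \qquad
z_{ij} = \sum_k x_{ik} \beta_{jk}
  + \sum_{h=1}^{n_h} \eta_{ih}\,(\lambda_{jh} + \lambda^{CWD}_{jh} c_i)
  + \varepsilon_{ij},$$

with $\varepsilon_{ij} \sim N(0,1)$ the unit-variance probit residual,
$\eta_{ih} \sim N(0,1)$ latent factor scores, and $c_i$ the standardized
water deficit of plot $i$. Because the species loadings are linear in
$c$, the residual covariance between two species is a quadratic function
of the deficit,

$$\Omega_{j_1 j_2}(c) = \sum_h (\lambda_{j_1 h} + \lambda^{CWD}_{j_1 h} c)
  (\lambda_{j_2 h} + \lambda^{CWD}_{j_2 h} c),$$

and the residual association is its correlation,
$R_{j_1 j_2}(c) = \Omega_{j_1 j_2} / \sqrt{\Omega_{j_1 j_1}\,\Omega_{j_2 j_2}}$.
Setting every $\lambda^{CWD}_{jh} = 0$ (`cwd_dependent = FALSE`) gives
the *static* JSDM used as the contrast model.

### Priors and sampling

The sampler (`fit_context_jsdm`) is a systematic-scan Gibbs sampler with
truncated-normal data augmentation for $z$, conjugate normal updates for
$\beta$ (prior $N(0, 10^2)$ per coefficient), the rows of $\eta$, and
the per-species pairs $(\lambda_j, \lambda^{CWD}_j)$ — updated jointly
because they multiply the same factor scores and are strongly dependent
a posteriori. The loadings carry a multiplicative gamma process
shrinkage prior: element precisions $\phi_{jh} \tau_h$ with
$\phi_{jh} \sim \text{Ga}(\nu/2, \nu/2)$ and
$\tau_h = \prod_{l \le h} \delta_l$,
$\delta_1 \sim \text{Ga}(a_1, 1)$, $\delta_{l>1} \sim \text{Ga}(a_2, 1)$.
$\lambda$ and $\lambda^{CWD}$ share the column precisions $\tau_h$ but
have separate local precisions.

Defaults are $a_1 = a_2 = 50$, $\nu = 3$, the convention of the
hierarchical community-modelling framework this model family comes from,
which makes later factor columns progressively negligible when the
truncation $n_h$ is generous. **When the factor count is fixed small and
known** — every validation run in this package uses $n_h = 2$ — that
convention is counterproductive: at 1,000 plots, $a_1 = a_2 = 50$ puts a
prior precision of roughly $50^2$ on the second column, shrinking
loadings of order one by two thirds and biasing every association shift
toward zero. The validation suite therefore runs with mild shrinkage
($a_1 = a_2 = 3$); users fitting real data with a generous truncation
should keep the stronger default.

The number of latent factors is a fixed truncation (no birth–death
moves), which keeps chains directly comparable for convergence
assessment. Default desk-scale schedule: 3 chains, 2,000 burn-in and
2,000 retained iterations; production analyses of continental data used
schedules three orders of magnitude longer, and those values can be set
in `mcmc_config()`.

### Covariate scaling

Predictors are centred and scaled before fitting; the constants are
stored in the fit and re-applied by `predict_unconditional()` and every
association function, so users always pass CWD in mm. The CWD inside
the loading term is standardized separately: on the raw mm scale
(hundreds of mm) $\lambda^{CWD}$ would be numerically tiny and mix
poorly. The synthetic-data generator uses the theoretical moments of its
uniform CWD distribution (mean $(a+b)/2$, sd $(b-a)/\sqrt{12}$); the
fitter uses empirical moments. The difference is $O(n^{-1/2})$ and
immaterial, but it is why truth-based checks use the generator's stored
constants.

## From posterior to inference

* `association_posterior()` evaluates $R$ per retained draw at chosen
  CWD values (mm).
* `classify_shift()` compares the wet and dry anchors — by default the
  25th and 75th percentiles of the plots' CWD — and classifies each
  unordered pair by $\Pr(R_{dry} > R_{wet})$: positive above .95,
  negative below .05, otherwise none. Exact ties (possible only in
  degenerate posteriors) count one half. The classification depends only
  on the per-draw indicator, so it is invariant to monotone relabelling
  of the association scale.
* `significant_associations()` keeps pairs whose equal-tailed 95%
  credible interval excludes zero, returning a $-1/0/+1$ matrix.
* `community_association()` computes
  $CA = (N_+ - N_-)/(N_+ + N_-)$ over the pairs matching a group
  combination; "overall" combinations take every pair with at least one
  member in the focal group. When no association is significant the CA
  is undefined and flagged — never silently zero.
* `ca_profile()` sweeps a CWD grid (default 50 points over the observed
  range). Two uncertainty modes are provided because the underlying
  convention is genuinely ambiguous: the *point estimate* uses the
  CI-filtered classification (matching the counting rule above), while
  the *band and `ca_draw_mean`* are draw-wise — per draw, every defined
  pair contributes the sign of its correlation. The CI-filtered point
  estimate demands 95% certainty per pair at a single gradient point and
  is conservative; the draw-wise mean is the better-powered instrument
  for trend direction and is what the validation suite uses for
  monotonicity checks.
* `delta_ca()` contrasts the static against the context-dependent model
  ($\Delta CA = CA_{static} - CA$; positive means the static model
  overestimates positive association).
* `stacked_richness()` sums $\Phi(x'\beta_j)$ over a species group along
  the gradient with all other covariates at their medians — richness
  without associations, used to verify that the deficit is a stress
  gradient for the sensitive group only. Quadratic columns are
  recomputed from the medians of their base columns rather than taking
  the median of the squares, so the profile stays on the fitted response
  surface.
* `residual_cwd_correlation()` checks that residuals from the
  unconditional predictions (latent factors integrated out analytically)
  are uncorrelated with the deficit — the guard against shifts driven by
  shared absences.

### Numerical conventions

Degenerate cases have defined, warned behaviour rather than crashes: a
species whose total loading vanishes at some CWD has undefined
correlations there (excluded from CA counts); PSRF of zero-variance
chains is 1; ESS of a constant sequence is its length; a perfectly
predicted species yields an undefined (not zero) residual correlation.
Credible intervals are equal-tailed quantiles (type 7); posterior means,
not medians, are the point summaries throughout. PSRF is the split-chain
Gelman–Rubin statistic; ESS uses Geyer's initial monotone
positive-pair truncation of the autocorrelation sum. The truncated
normal sampler switches to exponential rejection in the tails and is
exact for means at least 30 standard deviations inside the excluded
region.

## What the synthetic data emulate — and what they do not

`generate_truth()`/`generate_community()` run the generative model
forward: CWD uniform over 0–1,100 mm (the span of the European
dry-grassland gradient this model class was built for), other covariates
i.i.d. standard normal, Ellenberg moisture values stratified so the
drought-tolerant ($E_m \le 3$), intermediate, and drought-sensitive
($E_m \ge 5$) groups are always non-empty.

`sgh_truth()` plants a known stress-gradient pattern for validation,
with two latent factors. Drought-sensitive species share factor 1 with
total loading $0.6 + 1.2c$: negative at the wet end, rising through
zero, strongly positive when dry — so within-group associations move
from mixed to uniformly positive. Drought-tolerant species mirror this
on factor 2 with $0.6 - 1.2c$. Constant cross-loadings of alternating
sign ($\pm 0.8$) keep correlations away from the single-factor $\pm 1$
degeneracy and guarantee that both planted shift classes are non-empty
in every realization. Magnitudes were chosen once so the planted signal
survives probit attenuation (a loading of total magnitude $t$ is
observable only through $t^2/(t^2+1)$ of the latent variance) at 1,000
plots. Regression coefficients give sensitive species declining and
tolerant species increasing occupancy along the gradient, so the stacked
richness curves reproduce the expected turnover.

Because cross-group pairs inherit shifts only indirectly (through the
correlation normalization), the *planted directions* are the
within-group ones; validation checks therefore score within-group pairs
with true $|R_{dry} - R_{wet}| > 0.3$. Passing these checks shows the
machinery recovers a planted, well-identified signal at desk scale. It
does not show that real vegetation-plot data are this well behaved: the
generator has no spatial autocorrelation, no phylogenetic trait
structure, no missing covariates, and a uniform (not empirical) CWD
distribution.

## Water balance

`water_balance()` derives the climate covariates from monthly data:
Thornthwaite potential evapotranspiration with day-length correction
(temperature-only, matching the available inputs; the PET function is
pluggable), a single-bucket soil water model iterated to a periodic
steady state (monthly AET is `min(PET, precip + storage)`, storage
clamped to the available water capacity, convergence when the January
storage changes by less than $10^{-6}$ mm between years), and
growing-season sums over calendar May–August:
$CWD_{GS} = PET_{GS} - AET_{GS}$. Growing degree-days use base 5 °C,
freezing degree-days base 0 °C, both from monthly means weighted by
month length. Water mass closes exactly: precipitation equals AET plus
surplus over the converged cycle. Snow storage, sublimation and
radiation corrections are out of scope, so agreement with any particular
gridded CWD product is not claimed.

## Preprocessing conventions

`run_pipeline()` applies the filters in a fixed order: collinearity
pruning (greedy: among variables in a violating pair, drop the one with
the largest mean absolute correlation, never dropping protected columns
such as CWD), quadratic expansion (`<name>_sq`, idempotence guarded),
one random plot per grid cell, then the rare-species rule — a species
needs 10 presences per predictor, counting environmental variables
(quadratics included, intercept excluded) plus latent variables, e.g.
$10 \times (12 + 20) = 320$ presences for 12 environmental and 20 latent
variables. Subsampling precedes the rare-species filter because presence
counts are defined over the plots actually modelled.

## Problem sizes used in validation

The shipped validation suite runs, per scenario, communities of
800–2,000 plots and 5–15 species with 2 chains of 1,500–3,000 total
iterations, and 3 replicate communities for the recovery checks — sizes
at which the planted signals are comfortably identified and a full run
completes on a laptop in minutes. The same code paths scale to the
production schedules quoted above via `mcmc_config()`.

## Known limitations

Associations are not interactions: directionality cannot be estimated
from co-occurrence, and residual correlation can also reflect missing
covariates or shared dispersal limitation. The latent-factor truncation
is fixed, not adapted. Only binary occurrence is supported. The
loading–CWD relationship is linear; strongly hump-shaped association
profiles can only be approximated by the induced quadratic covariance.
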
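---
title: "Methods: HAZ distribution shifts, survey-age units, and the faltering simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HAZ distribution shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazshift)
```

# The scientific question

In low- and middle-income countries the population mean height-for-age
Z-score (HAZ) declines steeply from birth to about 24 months. Two mechanisms
could produce that decline, and they are distinguishable from the *shape* of
the cross-sectional HAZ distribution:

* **Subgroup faltering.** If only a high-risk subgroup falters, the
  distribution stretches: the SD grows, the lower tail (5th percentile)
  falls away from the mean faster than the upper tail, and the distribution
  skews negative.
* **Whole-population faltering.** If essentially all children falter, the
  distribution translates downward: mean, median, p5 and p95 fall together
  and the SD does not grow.

`hazshift` provides the three analysis layers needed to make this comparison
operational: distributional parameters per survey × age band, regression of
those parameters on the (sign-reversed) band mean, and a Monte Carlo
simulator that shows what each mechanism would do to the distribution.

# Survey-age units

## Banding

Children aged 0–36 months are grouped into 12 half-open bands
$[k w, (k+1) w)$ of width $w = 91.3$ days $= 365.25/4$. Three months is a
compromise: wide enough that each band holds enough children for stable tail
percentiles, narrow enough that the within-band decline of the mean does not
materially inflate the within-band variance. Because ages are integer days
and the width is not an integer, no age ever falls on a band boundary, so no
tie-breaking rule is needed. Ages at or beyond $12 w = 1095.6$ days are
flagged out of range and counted, not silently dropped. Sensitivity widths
are 30.44 days (= 365.25/12, with 36 bands) and 182.6 days (6 bands).

## Plausibility filter

HAZ values outside $[-9, 9]$ are biologically implausible and excluded
(counted per run); the stricter WHO-style bound $[-6, 6]$ is available as a
sensitivity switch. The filter keeps boundary values: exclusion is strictly
beyond the bound.

## Weighted distributional parameters

Each unit carries the survey-weighted mean, median, SD, 5th and 95th
percentile of HAZ, plus the tail distances $\Delta p5 = \text{mean} - p5$
and $\Delta p95 = p95 - \text{mean}$. With weights $w_i$ and total
$W = \sum w_i$:

* mean $= \sum w_i x_i / W$;
* SD $= \sqrt{\sum w_i (x_i - \text{mean})^2 / W}$ (the weighted
  *population* form; a frequency-weight divisor $W - 1$ is available via
  `banding_config(sd_divisor = "frequency")`, but at survey sizes the
  difference is negligible and the population form has the cleaner
  contract — exactly zero for a single observation);
* percentiles invert the weighted empirical CDF
  $F(x) = \sum_{x_i \le x} w_i / W$, linearly interpolating between the
  knots $(x_{(i)}, F_i)$ at the target probability; targets at or below
  $F_1$ return the smallest value. With equal weights this is exactly the
  ECDF-interpolation sample quantile (`stats::quantile` type 4), which is
  what the equal-weight reduction tests pin. For integer weights the
  estimator agrees with brute-force weight replication exactly for mean and
  SD, and at the cumulative-weight knots for percentiles; between knots any
  replicated sample quantile converges to the step-function inverse CDF, so
  the interpolating definition is a deliberate smoothing choice, documented
  here and frozen by tests at the knots.

The exact weighted-percentile rule used by survey software varies between
packages; this one was chosen because it is deterministic, order-statistic
based, and consistent for the population quantile.

Units whose child count falls below `min_children_per_unit` (default 1,
i.e. nothing dropped — a full-scale run keeps all 179 × 12 = 2148 units) can
be excluded because very sparse cells destabilise p5/p95; excluded children
are counted in the run manifest.

# Pooled age-band summaries

The international summary for a parameter in a band is the *unweighted* mean
over all units in the band — units deliberately do not get size weights
because the inference is about surveys, not children. The 95% CI accounts
for clustering of units by country with a cluster-robust (sandwich) variance
for an intercept-only model: with cluster score sums
$s_j = \sum_{i \in j} (y_i - \bar y)$ over $J$ countries,

$$\widehat{SE}^2 = \frac{J}{J-1} \cdot \frac{\sum_j s_j^2}{n^2},$$

with a normal critical value for $J \ge 30$ and $t_{J-1}$ otherwise. A
country random-intercept alternative is available
(`pool_age_band(..., method = "random_intercept")`). The sandwich form was
chosen as the default because it makes no distributional assumption about
country effects; its finite-sample coverage is verified by simulation in the
test suite (500 replicates of 40 exchangeable country clusters).

# Three-level models

For outcome $y$ (SD, median, $\Delta p5$ or $\Delta p95$) of unit $i$ in
survey $s$ in country $c$, with predictor $x = -(\text{mean HAZ})$ so that a
positive coefficient means the outcome rises as the mean falls:

$$y_{isc} = \beta_0 + \beta_1 x_{isc} + u_c + v_{0s} + v_{1s} x_{isc} +
\varepsilon_{isc}$$

with $u_c \sim N(0, \sigma^2_c)$, $(v_{0s}, v_{1s})$ bivariate normal with
unstructured covariance (surveys visibly differ in both level and slope, so
the covariance is left free), and $\varepsilon$ i.i.d. Estimation is REML
via `lme4::lmer` with the bobyqa optimizer; fixed-effect CIs use the normal
approximation, appropriate for thousands of units and tens of countries.
Convergence warnings and singular fits are carried on the result object
rather than silently ignored.

Numerical edge cases are handled explicitly rather than left to the
optimizer:

* if the outcome is an *exact* linear function of $x$ (residual SD below
  $10^{-8}$ relative to the outcome scale), REML is degenerate; the OLS
  coefficients are returned with all variance components zero;
* a single-survey dataset has no between-survey information; the fit falls
  back to OLS and every BLUP equals the fixed slope.

## ICCs

Under a random-slope model the between-cluster variance depends on $x$, so
an ICC is not uniquely defined. Following the convention that the reported
ICC describes clustering of the *level* of the outcome, ICCs are computed
from the intercept-relevant components at $x = 0$:

$$\text{ICC}_{country} = \frac{\sigma^2_c}{\sigma^2_c + \sigma^2_{v0} +
\sigma^2_\varepsilon}, \qquad
\text{ICC}_{survey|country} = \frac{\sigma^2_c + \sigma^2_{v0}}
{\sigma^2_c + \sigma^2_{v0} + \sigma^2_\varepsilon}.$$

An alternative (`icc_model = "random_intercepts_refit"`) refits a
random-intercepts-only model and reports its components. Interval estimates
for ICCs use a parametric bootstrap (`icc_bootstrap_ci()`); Wald intervals
for variance ratios behave poorly near the boundary, and the bootstrap is an
implementation choice documented as such.

## Stratified, per-survey, and BLUP slopes

Stratified slopes come from one interaction model per stratifier
(`y ~ 0 + stratum + stratum:x` plus the shared random structure), so strata
share variance components; strata contributing fewer than two surveys are
excluded and flagged. Stratifiers are world region, survey period, income
class, survey-size tertile and baseline-mean-HAZ tertile (tertiles computed
across surveys). Per-survey fixed-effects slopes are within-survey OLS fits
(equivalent to a saturated survey × $x$ interaction model), with $t$-based
CIs requiring at least 3 units and an explicit flag when a survey has no
predictor variation. BLUP survey slopes add the predicted random slope
deviation to the fixed slope; shrinkage guarantees they spread no more than
the OLS slopes, which the tests check empirically.

# The synthetic-data generator

Real DHS microdata are access-restricted, so the generator stands in for
them as a first-class, tested component. It emulates:

* **Scale.** 64 countries, 179 surveys; a quarter of countries contribute
  one survey, a fifth two, the rest more. Children per survey are drawn from
  a log-normal with meanlog $= \log 3159$ and sdlog $= 0.571$ — chosen so
  the median is 3159 and the interquartile range about 2495 — clipped to
  [351, 27352]. The log-normal reflects the strong right skew of real
  survey sizes.
* **Age structure.** Ages are sampled uniformly over [0, 1096) days. Real
  surveys report roughly constant counts per 3-month band, and nothing in
  the downstream analysis depends on the age density, so uniform is the
  simplest adequate choice.
* **HAZ.** Per-child HAZ is Gaussian around a survey-specific mean curve:
  a configurable population curve (default piecewise-linear from −0.4 at
  birth to −1.9 at 24 months, then flat) plus a zero-mean country intercept
  (SD 0.45), a zero-mean survey intercept (SD 0.25), and a mean-one
  per-survey multiplier on the age-related decline (SD 0.15). The country
  and survey SDs were set so that the spread of survey baseline means
  (0–3-month band) spans roughly −2 to +0.8 around −0.44, matching the
  emulated compilation. Because all survey-level perturbations are
  zero-mean, the configured curves remain the truth in expectation — the
  property the estimator tests rely on.
* **Measurement error.** An independent zero-mean Gaussian with age-specific
  SD (default 0.5 at birth declining to 0.2 at 36 months) is added to the
  true HAZ. This reproduces the stylised fact that observed HAZ SDs are
  larger in early infancy (gestational-age misclassification, birth-date
  recall, length measurement in infants) and produces the declining-SD
  band pattern through the downstream pipeline.
* **Weights.** Log-normal design weights (log-scale SD 0.5), independent of
  HAZ by default so weighted estimators are unbiased for the configured
  truth; a HAZ-correlated mode exists purely to stress-test the weighted
  estimators. Downstream normalisation is unnecessary because all weighted
  statistics are ratio estimators.
* **Covariates.** Region and income are assigned at country level and
  survey years per survey, with the categorical distributions of the
  emulated compilation (57% sub-Saharan Africa, 60% low income, more
  surveys in later periods).

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: cluster/household sampling stages within
surveys (weights are i.i.d. rather than design-derived), digit preference
and other data-quality artefacts, non-Gaussian HAZ shapes, birth
seasonality, and any dependence of measurement error on the child's true
size. Conclusions about estimator correctness transfer; conclusions about
substantive effect sizes do not.

# The faltering simulator

The simulated population starts as $N(0,1)$ HAZ for $n = 10{,}000$ children.
A fixed exposed fraction $p$ (assigned at baseline, never reassigned)
absorbs the whole population decline: per step each exposed child's decline
is drawn $N(d, (d/10)^2)$ with $d = 0.1/p$, so the population mean falls by
exactly 0.1 per step in expectation; 20 steps take the mean to −2. Each
scenario runs 1000 replications and averages mean, SD, p5 and p95 per step,
with Monte Carlo standard errors retained.

Choices the underlying description leaves open, and how they are resolved:

* **Decline distribution.** Normal with the stated mean and SD is the
  minimal reading; a truncate-at-zero switch (no growth spurts) exists and
  is off by default. At the default noise level truncation is irrelevant
  ($d/10 \ll d$).
* **Preferential selection.** "Preferentially selects low/high HAZ" is
  implemented as deterministic rank selection of the $p n$ lowest/highest
  baseline values — the reproducible extreme case; a probabilistic mode
  would interpolate between it and random selection.
* **Floor.** Children falling below HAZ −6 are removed from all subsequent
  summaries (died/censored); a clamp-at-floor mode is available but off by
  default.
* **Baseline-graded deficit.** $d_i = d(1 + \gamma (z_{0i} - \bar z_0))$
  with default $\gamma = 0.3$, centred on the exposed group's baseline mean
  so the population decline stays exactly $d$ per step. Only the direction
  (taller children falter more) is given by the hypothesis being modelled;
  $\gamma$ sets how fast the distribution narrows, and 0.3 keeps the
  variance positive throughout the 20 steps ($k d \gamma < 1$).

For random selection without floor or gradient, the population at step $k$
is a two-component Gaussian mixture with exact moments: exposed mean
$-k d$, exposed variance $1 + k (d/10)^2$, population mean $-0.1 k$ and
population variance

$$(1-p) + p\left(1 + k (d/10)^2 + (k d)^2\right) - (0.1 k)^2 .$$

`mixture_moments_oracle()` implements this closed form and refuses
scenarios outside its domain. The test suite requires the simulated mean
and SD at every step to sit within 3 Monte Carlo standard errors of the
oracle for all four exposure fractions; at step 20 the oracle SDs are
3.607, 2.237, 1.528 and 1.001 for $p$ = 25/50/75/100%. Smoothing of the
step-wise trajectories is cosmetic and not applied; reported values are raw
per-step averages, and the final-step value is the quantity quoted at
"mean HAZ = −2".

# Determinism and problem sizes

Every stochastic function takes a seed; the pipeline derives per-stage seeds
from one global seed as `(seed * 7 + stage * 1000003) mod (2^31 - 1)`, so
stages are independently reproducible and two runs with the same
configuration produce byte-identical CSVs. The test suite verifies
generator reproducibility bit-for-bit.

Simulation-based checks in the test suite use deliberately chosen problem
sizes: slope-recovery coverage uses 300 replicates of 100 surveys × 12
units; pooled-CI coverage uses 500 replicates of 40 countries × 6 units;
the reference simulator runs use the full 10,000 children × 1000
replications; most other tests run on 2–12 surveys of a few hundred
children. These sizes keep each check's Monte Carlo error well below the
tolerance it asserts.

# Known limitations

* The weighted SE of the pooled band mean treats units as exchangeable
  within country; surveys contributing more bands implicitly get more
  weight in the pooled mean (as intended: units, not surveys, are the
  datapoints).
* ICCs from random-slope models are predictor-value-specific; the reported
  values describe $x = 0$ only.
* The generator's independence of weights and HAZ makes weighted and
  unweighted estimators agree in expectation, so it cannot by itself
  demonstrate the *value added* by weighting on informative designs; the
  HAZ-correlated weight mode exists for that purpose but is not part of the
  default checks.
* The simulator is an abstract population model: no ages, births, deaths
  (other than floor censoring) or covariates. It answers what a faltering
  mechanism does to a distribution, not what any particular country's data
  will look like.
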
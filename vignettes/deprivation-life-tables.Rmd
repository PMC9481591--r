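---
title: "Deprivation-specific life tables from small-area mortality counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deprivation-specific life tables from small-area mortality counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deplife)
```

## The problem

Net survival and other population-based cancer survival measures require
*expected* (background) mortality from life tables that are specific to sex,
age and — because mortality varies strongly with socioeconomic status — area
deprivation. National statistical offices typically release small-area death
and population counts only in abridged form: 5-year age bands (0–4, 5–9, …,
85+) per census tract, sex and calendar year, with tract populations around a
thousand people. At that granularity the raw rates are far too noisy to build
tract- or quintile-specific life tables directly, so the rates must be
smoothed by a model before the demographic machinery is applied.

`deplife` implements that workflow end to end:

1. descriptive statistics — crude rates with exact Poisson intervals,
   indirectly standardized mortality ratios, a calendar-trend test;
2. a Poisson mixed-effects smoothing model of the abridged counts with a
   restricted cubic spline of age, deprivation-quintile effects, a full
   spline-by-quintile interaction and a census-tract random intercept;
3. complete (single-year) life tables and life expectancy at birth and at
   age 75 per quintile and per tract, with delta-method uncertainty on the
   smoothed rates;
4. population-weighted aggregation of tract life expectancy to provinces and
   rank-based life-expectancy quintile maps.

Because the real census-tract cession cannot be redistributed, the package
ships a synthetic census-tract generator with a *known* hazard, which turns
every stage into a testable claim: the model's life expectancy estimates can
be compared against an exact integral of the generating hazard.

## The smoothing model

Within each sex, the death count of tract $j$ in age band $a$ and quintile
$q$ is modelled as

$$ d_{jaq} \sim \mathrm{Poisson}\!\left(P_{jaq}\,\lambda_{aq}\,e^{u_j}\right),
\qquad
\log \lambda_{aq} = \beta_0 + f_1(x_a) + \sum_{k=2}^{5}\beta_k\,[q=k]
  + f_2^{(q)}(x_a), \qquad u_j \sim N(0, \sigma_u^2), $$

where $x_a$ is the band's representative age, $P$ the person-years offset,
$f_1$ a restricted cubic spline of age and $f_2^{(q)}$ the full interaction
(every spline column crossed with every non-reference quintile indicator).
The tract intercept $u_j$ captures non-spatial between-tract variation and
acts as a penalized smoother across tracts.

Design choices a user should know about:

* **Representative age.** Closed bands use their midpoint
  (`age_lower + 2.5`); the open 85+ band is assigned age 90, an
  approximation to the deaths-weighted mean age in that band. Both are
  configurable (`build_design(open_band_age = ...)`).
* **Spline basis.** Harrell's restricted cubic parameterization: a linear
  column in `age − center_age` (default centring 60) plus truncated-cubic
  columns normalized by the squared boundary-knot span, linear beyond the
  boundary knots. Default knots `{2, 12, 22, 32, 42, 52, 67, 82}`;
  `select_knots()` re-derives them on new data by 5-fold cross-validation
  (folds stratified by quintile and age band), scoring candidates by the
  mean absolute error between held-out pooled stratum rates and predicted
  rates. The error is computed on rates pooled by quintile and band, not on
  individual tract rows, because most tract-level cells contain zero deaths
  and a row-level absolute error would reward systematic under-prediction.
* **Estimation.** The marginal likelihood is maximized under a Laplace
  approximation: an inner penalized IRLS Newton loop jointly updates the
  fixed effects and all tract intercepts at fixed $\sigma_u$ (the
  random-effect Hessian is diagonal, so each step costs one dense solve in
  the fixed-effect dimension via a Schur complement), and an outer
  one-dimensional Brent search maximizes the profiled objective over
  $\sigma_u$, using the numerically stable form
  $\ell_{\mathrm{Pois}} - \|\hat u\|^2/2\sigma^2 -
  \tfrac12\sum_j \log(1+\sigma^2 d_j)$ whose $\sigma \to 0$ limit is the
  ordinary Poisson GLM. The inner loop declares convergence when successive
  penalized log-likelihoods differ by less than `tol` (default `1e-8`,
  at most 200 iterations), uses step halving, and reports failure
  explicitly. The fixed-effect covariance is the corresponding block of the
  inverse joint Hessian at the optimum, conditional on $\hat\sigma_u$.
* **Weak identification.** Childhood cells frequently contain no deaths at
  all for some quintile; the corresponding interaction directions are then
  only weakly identified and the Newton equations can become numerically
  singular mid-iteration. The solver adds an escalating ridge *only as a
  fallback for the linear solve* (damping the step, not the optimum), and
  the covariance solve uses the same guard, which yields honestly enormous
  standard errors in those directions. Predicted single-year rate schedules
  are floored at $10^{-12}$ per person-year so a numerically zero childhood
  rate cannot invalidate a life table.
* **Prediction.** Quintile-level predictions set the random intercept to 0
  (the median tract); tract-level predictions add the tract's
  empirical-Bayes intercept. Setting `re_mode = "average"` instead
  multiplies quintile rates by $e^{\sigma_u^2/2}$, the mean over the tract
  frailty distribution — the two conventions answer different questions
  (typical tract vs. population-average) and the choice is a config flag.
  95% intervals are delta-method intervals on the log-rate,
  $\exp(\hat\eta \pm 1.96\,\sqrt{x^\top V x})$.

## Life-table construction

The spline model is continuous in age, so the package builds *complete*
(single-year) tables from predicted rates at interval midpoints, ages 0–99,
with an open interval at 100 (predictions beyond the last knot extrapolate
the spline's linear tail). Single-year construction minimizes sensitivity to
the separation-factor convention; an abridged constructor
(`rates_to_lifetable_abridged()`, $n = 5$, $a = n/2$) is provided for
comparison. Conventions: $a_0 = 0.1$ (low-mortality infant convention),
$a_x = 0.5$ otherwise, radix 100,000, $q = m/(1+(1-a)m)$ capped at one, and
open-interval closure $q = 1$, $L = l/m$. The authors of comparable national
tables rarely publish their separation factors, so validation rests on
oracles rather than on reproducing any published table to the second
decimal.

Province life expectancy is the person-years-weighted mean of tract life
expectancies (weights are the tract's total person-years over the period) —
not a life table built from pooled province rates, which is a different
estimand; the pooled-rate alternative can be obtained by running the
life-table stage on province-aggregated counts. Life-expectancy quintiles
are rank-based with bin sizes differing by at most one and ties broken by
unit identifier.

## The synthetic generator and its defaults

`generate_tracts()` emulates the census-tract structure of the target data:
quintiles assigned by rank of a simulated deprivation score (exactly
⌊n/5⌋–⌈n/5⌉ tracts per quintile), tract totals log-normal around a mean
population of 1,311 with log-sd 0.5 (the inter-tract dispersion is not
published; this choice is ours and only positivity and coverage matter for
correctness), a fixed European-style age pyramid scaled to each tract, a
50/50 sex split and calendar years 2011–2013.

`simulate_counts()` draws one frailty per tract,
$u_j \sim N(0, \mathrm{sd}^2)$ shared across sexes and years, and Poisson
deaths with mean `person-years × band-average rate × e^u`. Band-average
rates integrate the hazard over the band; the open band uses the
survival-weighted average, which makes the open-interval closure exact for
the true hazard.

The generating hazard is Gompertz–Makeham,
$h_0(x) = c + b\,e^{\theta x}$, multiplied for quintile $k$ by
$\exp\{(a_k + s_k x)\, w(x)\}$. The age profile $w$ is, by default, a
strictly positive Gaussian window centred at age 50 (width 28 years): the
deprivation gradient is weak in childhood, widest at ages 30–70 and fades at
the oldest ages, the pattern consistently reported for area-deprivation
mortality differences. A purely log-linear interaction
(`age_profile = "linear"`) cannot reproduce that non-monotone pattern, which
is why the window exists; setting it to `"linear"` recovers exact
proportional hazards for testing. Default calibration targets realistic
Southern-European values — female/male life expectancy at birth of
84.3/79.2 years in the least deprived quintile with Q1–Q5 gaps of 3.2/3.8
years — found by root-finding the Gompertz level and the quintile-effect
scale against the exact survival integral (`true_life_expectancy()`,
composite trapezoid, step 0.01 years, upper bound extended until survival
falls below $10^{-9}$). Default frailty sd is 0.12 on the log-rate scale, a
modest between-tract residual variation.

What the generator deliberately does *not* emulate: infant-mortality humps,
accident humps, migration, spatially correlated frailty, calendar trends,
and real census geography. Passing tests therefore demonstrate correctness
of the estimation machinery under a smooth, well-specified hazard — not
robustness to every feature of real vital-statistics data.

## Validation design and problem sizes

All validation is against computable oracles, with simulation sizes chosen
so Monte-Carlo error is well below each tolerance:

* *Life-table oracle*: tables built from true band rates agree with the
  fine-grid survival integral within 0.15 years for every quintile and sex
  (the residual ≈0.1 year reflects the $a = 1/2$ within-interval convention
  against an exponentially growing hazard, not a coding error).
* *Reduction oracle*: the mixed fit with $\sigma_u = 0$ matches an
  independent IRLS Poisson GLM coefficient-for-coefficient within $10^{-6}$
  on well-identified designs; `lme4::glmer` serves as an independent GLMM
  cross-check.
* *Gap recovery*: with built-in Q1–Q5 gaps of 2, 3.5 and 5 years, 20
  replicates of 1,500 tracts × 3 years recover the gap with mean absolute
  error below 0.3 years and the correct sign in every replicate. (At a few
  hundred tracts the per-replicate noise — dominated by sparse childhood
  deaths and tract frailty — is several tenths of a year, so the replicate
  size is what MC error requires for that tolerance.)
* *Frailty recovery*: $\hat\sigma_u$ over 20 replicates of 500 tracts is
  within 3 MC standard errors of the generating 0.3; the small Laplace/EB
  downward bias is visible but well inside that band.
* *Delta-method calibration*: a 500-replicate parametric bootstrap around a
  fitted model (100 tracts × 3 years) yields 93–97% empirical coverage of
  the 95% intervals at twelve well-supported age-quintile points.
* *Knot placement*: cross-validation prefers knots bracketing a strong
  hazard bend (a Makeham floor crossing the Gompertz rise near age 77) over
  knots crammed below age 12 in ≥90% of replicates. With a *pure* Gompertz
  truth the old-age log-rate is linear, any candidate fits it, and CV
  correctly prefers parsimony — knot placement is only decidable when the
  truth actually bends, which is what this experiment encodes.
* *Age gradient*: on default synthetic data (2,000 tracts, both sexes) the
  extreme-quintile contrast of population-weighted predicted rates — the
  Q5 − Q1 log-rate gap, used instead of a max–min spread because the
  latter's maximum over five noisy estimates is biased upward exactly where
  deaths are sparse — peaks at ages 30–70 and is smaller both under 15 and
  at 85+, and the spread of tract-level life expectancy at 75 is smaller
  than at birth.

## Known limitations

* The Laplace/PIRLS profile slightly underestimates $\sigma_u$ in small
  samples (a known property of the approximation); adaptive quadrature is
  unnecessary here because every tract contributes many cells.
* Childhood rates for individual quintiles are weakly identified at
  realistic tract counts; quintile-level life expectancy absorbs this as
  noise of a few tenths of a year, and tract-level maps should be read
  accordingly.
* Predictions above age 99 are linear-tail extrapolation; the open-interval
  closure at 100 slightly overstates survival under a still-accelerating
  hazard, an effect that cancels in between-quintile gaps.
* The trend test operates on yearly totals per sex; with only three years it
  has power against strong trends only.
* Under the female parameterization (steeper Gompertz slope, deaths
  concentrated beyond the last spline knot, where the quintile interaction
  is linear-tail extrapolation) the estimated Q1–Q5 gap runs a few tenths
  of a year below the generating gap and carries ±0.3 years of noise even
  at thousands of tracts; the male parameterization is nearly unbiased.
  Gap-recovery guarantees are therefore stated for the male setting.
* A proportional-style quintile effect large enough to produce a
  3.2-year female life-expectancy gap implies an all-age standardized
  mortality ratio around 1.2 for Q5 — larger than the ≈1.1 typically seen
  for women in real data, whose deprivation effect has a different age
  pattern than this generator's single smooth window. Synthetic SMRs should
  be read with that in mind.
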
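---
title: "Methods: panel estimation of coal-plant health externalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel estimation of coal-plant health externalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalcough)
```

## The design and its assumptions

`coalcough` implements a difference-in-differences design for the effect of
newly commissioned coal plants on household respiratory morbidity. Exposure
varies at the district level: `x_dt` is the count of coal plants a district
gained between two survey rounds, zero for everyone in the first round.
The outcome is a binary household indicator (reported cough), and the
estimating equation is a linear probability model with a household (or PSU)
fixed effect and a survey-round fixed effect:

$$y_{ipdt} = \beta x_{dt} + \theta_1' D_{ipdt} + \theta_2' H_{ipdt}
  + \alpha_{ipd} + \gamma_t + \varepsilon_{ipdt}.$$

Identification rests on parallel trends: absent new plants, treated and
untreated districts would have followed the same cough trajectory. The
package ships the corresponding diagnostic battery — baseline balance in the
first wave, pre-program trend regressions on district census changes
(including their first principal component), falsification outcomes (fever,
diarrhea) that coal smoke should not affect, a non-coal-plant placebo
exposure, migration exclusions against avoidance behavior, and
electrification outcomes — because in this design the diagnostics *are* the
evidence that the estimate means what it claims.

A linear probability model is used deliberately: with a binary outcome and
household fixed effects, within-group demeaning plus OLS gives
percentage-point effects directly comparable across specifications, and the
two-period conditional logit (`fit_conditional_logit()`) is available as a
functional-form check on the odds-ratio scale.

## Estimator details

**Within transform.** Fixed effects are absorbed by demeaning every design
column within its group (`within_transform()`). Groups of size one become
zero rows; they contribute nothing to the estimate but are retained so
reported observation counts match the input.

**Collinearity.** The demeaned design is rank-checked by QR. When columns
are collinear they are dropped greedily, with the round fixed effect given
priority over the treatment: a treatment collinear with the round effect
(e.g., every district treated identically) is an identification failure and
raises a degenerate-design error naming the column, rather than silently
absorbing the time trend. Dropped controls are reported in
`dropped_collinear`.

**Cluster-robust variance.** `cluster_robust_vcov()` computes the sandwich
$(X'X)^{-1}\left(\sum_g X_g'e_ge_g'X_g\right)(X'X)^{-1}$ with the CR1
factor $\frac{G}{G-1}\cdot\frac{N-1}{N-K}$. The default cluster is the PSU,
the survey's first-stage sampling unit; district clustering is available via
`regression_spec(cluster_level = "district")`. `K` counts the estimated
slope parameters only. Absorbed fixed-effect groups are *not* counted when
they nest within clusters: counting the ~N/2 household intercepts of a
two-period panel would inflate standard errors by about $\sqrt{2}$, and in a
200-replicate calibration study of the default generator it pushed the
nominal-95% interval's coverage of the true effect to 100%; with the
nested-cluster convention coverage is ≈95–97%. The dummy-equivalent
convention remains available through the `k_absorbed` argument. Two-sided
p-values use the normal reference by default (`p_reference = "t"` switches
to $t_{G-1}$).

**Conditional logit.** For two waves, the conditional likelihood of the
fixed-effects logit depends only on households whose outcome changes; it
reduces to a logistic model of "switched up" on within-household covariate
differences (the round effect enters as the constant difference).
Newton–Raphson on the analytic score is run to a gradient norm of 1e-9 with
at most 100 iterations; non-convergence and the no-switchers case raise
classed errors. Odds ratios are reported with delta-method standard errors.
The implementation is cross-checked in the tests against exhaustive
enumeration of within-household outcome arrangements and against
`survival::clogit`.

## Randomization inference

`randomization_inference()` reassigns the binary "gained a coal plant"
indicator uniformly (without replacement) over districts, keeping the
treated count fixed, and re-estimates the same specification per replicate.
Reassignment at the district level preserves any within-district outcome
correlation, which makes the test conservative. Conventions, fixed here
once: the one-sided p-value is the strict-exceedance count divided by `R`
(the add-one convention `(count+1)/(R+1)` is an option), and the observed
assignment is not excluded from the sampling space. The default replicate
specification is the no-controls, household-plus-round-fixed-effects model;
for that case replicates are computed through an algebraic identity —
two-period household-FE OLS with a district-level binary regressor equals
the difference in district-aggregated mean household outcome changes — which
the tests verify against full re-fitting. Any other specification is
re-fitted in full.

## Dose–response

`fit_dose_response()` replaces the plant count with gained capacity in MW
divided by `capacity_scale` (default 1,000, so the linear coefficient is
the effect of a GW), optionally adding its square. The capacity cap drops
*entire districts* above the cap while keeping all unexposed districts —
the estimand is the dose–response over the lower part of the exposure
distribution, not a censored treatment. The quadratic uses raw polynomial
terms; collinearity is left to the estimator's rank check.
`capacity_coverage()` reports the household-weighted CDF of capacity among
exposed households.

## The cost calculator

`compute_cost()` converts a per-plant effect β (extra cough episodes per
person-year) into discounted money terms:

* annuity factor $\sum_{t=1}^{T}(1+r)^{-t}$ with the ordinary (end-of-year)
  convention — at the default $r=3.81\%$ (the sovereign borrowing rate) and
  $T=20$ years this gives 13.82 discounted years, hence a 2-million-person
  district accumulates 27.6m discounted person-years; the annuity-due
  variant is available via `annuity_timing`;
* episodes = β × person-years; out-of-pocket costs at Rs 550/episode,
  converted at the market rate (Rs 60/\$) and the 2011 PPP rates for
  individual consumption (Rs 14.0/\$) and health (Rs 5.2/\$);
* missed work/school days at 4.09 per episode, valued at Rs 159/day (a
  deliberately conservative floor: the lowest state workfare wage) and
  converted at the consumption PPP rate;
* the headline total is out-of-pocket at consumption PPP plus the valued
  days.

The default β is 0.0106 — the un-rounded fixed-effects point estimate —
rather than the rounded 0.01; the package's own oracle test verifies that
the dollar lines are jointly consistent with 0.0106, and either value can be
passed. All fields are linear in β except the person-year quantities.
`cost_from_sample()` reduces raw episode-cost and episode-day vectors by
mean or median first; with right-skewed cost data the median variant is
substantially cheaper, which is why both are exposed. Full precision is kept
internally; rounding happens only in `print()`.

## The synthetic survey generator

`generate_panel()` emulates the structure the analysis assumes, with known
truth so recovery can be tested:

* **Nesting and scale.** 389 districts, 46 of which gain at least one coal
  plant; 6 PSUs per district and 17 households per PSU (≈2,300 PSUs,
  ≈39,700 households, ≈79,400 household×wave rows), matching the order of
  magnitude of a national two-wave panel with ~2,400 PSUs and ~40,000
  households.
* **Outcomes.** Cough is Bernoulli with probability
  `baseline + α_i + controls + trend·t + β·x_dt`, clipped to [0,1]:
  baseline 0.098, secular trend −0.016, β = +0.01 per plant. Fever
  (0.488, +0.127) and diarrhea (0.046, small decline) have zero coal
  coefficients by default, as do non-coal plants — they exist to be
  falsification outcomes. If more than 1% of implied probabilities need
  clipping, the configuration is rejected.
* **Household effects.** α is zero-mean normal, held fixed across waves. Its
  dispersion is anchored at SD 0.03 for a 9.8%-prevalence outcome and
  shrinks proportionally for rarer outcomes, so low-baseline outcomes do not
  pile up at the zero bound.
* **Plant counts and capacity.** Treated districts draw their plant count
  from {1: 0.70, 2: 0.20, 3: 0.05, 4: 0.05} (most treated districts gain
  one plant; a few gain several). District capacity gains are assigned from
  a mix with mass at 250/300/500 MW and a tail to 1,980 MW, applied by
  largest-remainder quota with a seeded shuffle so the documented exposure
  distribution — over half of exposed households at 250/300/500 MW, 80% at
  ≤600 MW, 90% at ≤1,000 MW — holds in every realization rather than only
  in expectation over 46 draws (an iid `"sample"` mode exists). For
  dose–response studies, `beta_capacity` (and `beta_capacity2`) switch the
  treatment term to a capacity dose with known slope/curvature.
* **Migration.** Mover status is a household-level trait (default 1.5%,
  below the 2% the design relies on), reported in one of the two waves,
  missing for a 0.2% sliver, and independent of treatment by default;
  `migration_treatment_shift` injects confounded migration to test the
  exclusion logic.
* **Census changes.** District-level pre-period changes are drawn
  independently of treatment under the null (parallel pre-trends hold by
  construction); means follow the untreated-district constants of the
  design's pre-trend table and SDs are backed out from those constants'
  standard errors (≈ se × √343). A configurable confound slope exists for
  power-testing the diagnostic.

What the generator does **not** emulate: survey weights and stratification,
the real geographic distribution of plants, district- or PSU-level common
shocks (beyond the PSU-constant urban indicator), serial dependence in
controls, item nonresponse outside the migration question, or
individual-level outcomes. Consequently, passing tests demonstrate that the
estimator, inference and diagnostics are correct and correctly sized for
this data-generating process — not that the design is robust to, e.g.,
unmodeled district-level shocks, where PSU-clustered standard errors would
be too small and district clustering should be preferred.

## Numerical and reproducibility choices

* One integer seed drives everything; per-stage child seeds are drawn
  *through* the generator (`sample.int` after seeding, with state restore)
  rather than by seed arithmetic — during development, generation seeds in
  arithmetic progression with a large increment produced measurably
  correlated Mersenne–Twister streams (a z ≈ −3 bias in a null treatment
  contrast over 100 replicates), which RNG-derived child seeds eliminate.
* Identical configuration and seed reproduce every table and report file
  byte for byte (tested).
* QR rank tolerance 1e-9; within-group means of demeaned columns are zero
  to 1e-10 (tested); missing values in requested columns are an explicit
  error, with listwise deletion available only through the documented
  migration filters.
* Degenerate inputs raise classed conditions (`coalcough_degenerate_design`,
  `coalcough_inference_error`, `coalcough_inestimable_error`, ...) so
  callers can distinguish identification failures from usage errors.

## Problem sizes used by the test suite

The calibration studies run at the design's own scale: 200 generator
replicates of the full 389-district survey for effect recovery and CI
coverage; 200 null replicates of a reduced 100-district survey (12 treated)
with R = 500 for the size of the randomization test; 40 replicates each for
dose–response slope recovery (truth 0.034 per GW, fitted on the ≤1,000 MW
subsample) and for sign-recovery of a concave response
(`beta_capacity = 0.12`, `beta_capacity2 = −0.05` per GW², chosen so the
curvature is clearly detectable at this scale while the response stays
positive and saturates above ~1.2 GW, as concentration–response theory
suggests). The whole suite runs in a few minutes on one core.

## Known limitations

* No survey weights or multi-way clustering.
* The conditional logit reports classical (inverse-Hessian) standard
  errors; clustered logit inference is out of scope.
* The dose–response treats capacity as a pollution proxy; actual emissions,
  abatement and wind patterns are unobserved, so the estimand is the
  reduced-form effect of capacity.
* The cost calculator values only out-of-pocket treatment and missed days —
  a deliberate lower bound that ignores illness disutility, mortality and
  effects outside the plant's district — and ignores population growth.
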
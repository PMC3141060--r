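---
title: "Methods: trial-based cost-effectiveness analysis with bootstrap PSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with bootstrap PSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## The problem

Randomized trials in critical care increasingly carry an economic
companion study: alongside the clinical endpoints, per-patient healthcare
costs and quality of life are collected so that the incremental
cost-effectiveness of one strategy over another can be estimated with its
full sampling uncertainty. `trialcea` implements such an evaluation for a
two-arm comparison — the motivating case is pulmonary artery catheter
(PAC) versus central venous catheter (CVC) monitoring in acute lung
injury — as a reusable, tested pipeline: per-patient cost streams,
quality-adjusted survival, lifetime projection with discounting, and
bootstrap probabilistic sensitivity analysis (PSA).

Because the underlying trial's patient records are not publicly
deposited, the package includes a first-class synthetic cohort generator
calibrated to the published summary statistics. Every downstream stage is
exercised and tested against that generator.

## Per-patient streams

**Costs to one year.** Each patient accrues (i) hospital cost — in real
use calculated from itemized bills as Σ department charge × department
cost-to-charge ratio (`hospital_cost()`); the generator draws it directly
— (ii) post-discharge direct medical costs, and (iii) lost wages, all in
2010 US dollars (a CPI table, `index_to_2010()`, converts other years;
the bundled factors are approximate and editable). Post-discharge costs
apply unit-cost weights to resource-use counts (`cost_weights()`,
`post_discharge_cost()`):

| category | weight |
|---|---|
| home oxygen | $600 first day + $6.50/day thereafter |
| home help | $100/day |
| rehabilitation | $800/day |
| skilled nursing facility (ventilated) | $1500/day |
| ED visit | $800/visit |
| physician visit | $200/visit |
| re-hospitalization | $1500/day + $1100/ICU day + $200/ventilated day |
| medications | $10/day |
| lost work | $200/day |

The re-hospitalization ICU and ventilator terms are encoded as *additive
increments* over the base day rate (2600 − 1500 and 2800 − 2600), so one
ICU + ventilated day costs $2800. Interview-reported medication counts
are converted to medication-days at 30 days per medication upstream in
the generator — a declared assumption, since the weights price days while
interviews count medications. Lost wages accrue only over reported lost
work days; no productivity loss is imputed after death, keeping the cost
perspective's "lost wages" a survivor quantity. ED visits are priced per
visit (the weight table's "per day" and the interview's visit counts are
reconciled in favor of visits).

**Effects to one year.** The one-year effect is the area under the
utility curve, in quality-adjusted days
(`utility_auc()`, `one_year_effect()`):

* linear interpolation (trapezoid) between completed interviews — the
  minimal convention for "area under the curve";
* carry-forward of the last observed value to day 365 (or death);
* utility steps to 0 exactly at death;
* before the first interview, the default carries the first observed
  value back to day 0 (`hospital_phase = "carry_back"`). Whether utility
  during the index hospitalization should instead be zero is not
  decidable from summary publications, so both conventions are
  implemented; `"zero"` nulls the pre-first-interview rectangle.
* patients discharged alive with no completed interview receive the
  arm-wave median trajectory; the count of such imputations is attached
  as an attribute and logged in the run manifest.

Survival curves use the Kaplan-Meier product-limit estimator
(`km_estimate()`, computed via the survival package; the test suite
checks it against an exhaustive hand computation on all four-patient
configurations).

## Lifetime projection (the reference case)

Survivors at day 365 are projected over their remaining life expectancy
from an age-, sex- and race/ethnicity-specific life table
(`remaining_life_expectancy()`: nearest-band lookup, oldest-band clamp
with a warning, unknown races fall back to `other`). Beyond one year a
survivor accrues a constant utility (default 0.6) and a constant annual
healthcare cost, both discounted at 3%/year for costs and effects
(`discounted_annuity()`):

$$PV = \sum_{t=1}^{\lfloor y \rfloor} \frac{a}{(1+r)^t}
      + (y - \lfloor y \rfloor)\,\frac{a}{(1+r)^{\lceil y \rceil}}$$

Conventions chosen where the field leaves them open: discounting starts
at the end of the first projected year, and the fractional final
life-table year is prorated linearly. Decedents within year one keep
their one-year totals. A life-expectancy multiplier (default 1.0)
supports sensitivity analysis on expected survival; no excess post-ALI
mortality is applied in the reference case.

Two bundled inputs are explicitly *not* empirical estimates: the annual
post-year-one cost defaults to a $5,000/yr placeholder (the survey-based
value used in published analyses is not in the public record) and the
bundled life table is synthetic — a Gompertz hazard
$\mu(x) = a\,e^{bx}$ ($a = 6.7\times10^{-5}$, $b = 0.09$, proportional
sex and race multipliers) integrated numerically, giving realistic
magnitudes (e.g. ~24 remaining years for a 50-year-old white male) and
age-monotone expectancies. Users should drop in official period life
tables in the same CSV schema for substantive work.

## Probabilistic sensitivity analysis

The default PSA is a nonparametric patient-level bootstrap within arm —
the standard design for trial-based economic evaluations, since the
publication names only "Monte Carlo simulated trials". Each of the 5000
trials resamples each arm with replacement to its original size and
recomputes the arm means; per-patient lifetime costs are winsorized at
the 95th percentile *within the resample* before averaging
(`winsorize_p95()`), costs only — whether effects were also winsorized is
unstated, and cost outliers are the motivating problem. A parametric
mode (`psa_parametric()`) instead draws arm-level means from normal
distributions with supplied means/SDs — the route to reconstructing
published summary-level results — with an optional within-arm
cost-effect correlation (default 0; published acceptability plateaus
suggest the real data had positive dependence, which summary statistics
cannot recover).

From the cloud of (ΔC, ΔE) pairs the package reports:

* quadrant probabilities (`quadrant_probs()`), with the *dominated*
  corner ΔC > 0 ∧ ΔE < 0; boundary conventions make the four regions an
  exact partition;
* threshold exceedance P(λΔE − ΔC < 0) and the acceptability curve
  P(λΔE − ΔC ≥ 0) on a willingness-to-pay grid (default $0–1000k/QALY in
  $10k steps). Dominated trials exceed every threshold; trials in the
  southwest quadrant are ranked by net monetary benefit, never by the
  sign-trapped raw ICER;
* a point estimate with classification; an ICER is reported only for
  tradeoffs, since a ratio is uninformative for dominated or dominant
  strategies;
* the 95% confidence ellipse from the cloud's mean and covariance at the
  χ²(2) quantile (`confidence_ellipse()`), cloud-based rather than a
  delta-method normal approximation.

Subgroup analyses (`run_subgroups()`) re-run the full PSA inside each
prespecified stratum — age (<45, 45–64, >64), sex, race/ethnicity, fluid
strategy, APACHE III (cut 90), tidal volume (cut 6.9 mL/kg), delay to
protocol (cut 21.5 h), and diagnosis. Ties at a cut go to the lower
stratum, matching the usual "≤" row labels; the diagnosis strata are
overlapping selections, not a partition. One-way sensitivity analyses
(`run_sensitivity()`) rebuild costing and projection under each
scenario — life expectancy ×0.5, post-year-one utility ×0.75/×1.25,
discount 5%, annual cost ×0.5/×2, physician-visit weight ×0.5/×2 (the
closest implementable surrogate for "physician reimbursements") — at the
same seed, and report percent changes against the reference.

## The synthetic cohort generator

`generate_cohort()` emulates, per arm of default 300 patients:

* **survival**: a two-piece exponential with hazards solved exactly from
  the two published KM anchors (piece break at day 60,
  `solve_piecewise_hazards()`) — the minimal model uniquely identified by
  two anchors. Defaults: PAC S(60) = 0.738, S(365) = 0.644; CVC 0.749,
  0.681. Censoring is administrative at day 365.
* **hospital costs**: log-normal matched by moments (PAC $96.8k ± 86.8k,
  CVC $89.2k ± 74.5k) — heavy right tails because the SDs approach the
  means. Length of stay is log-normal (means 24.4/23.8 d, SDs
  19.2/19.8 d); discharge day is min(death, LOS), a declared assumption
  since enrollment-to-discharge distributions are unpublished.
* **utilities**: interviews at days 61/183/274/365 (2/6/9/12 months at
  30.4375 d/month), only for patients alive at the wave, kept with
  per-wave completion probabilities 0.75/0.75/0.80/0.80 (chosen once to
  match the ~81% any-interview margin). Values are logit-normal around
  the wave medians (PAC 0.47→0.55→0.61→0.61, CVC 0.51→0.60→0.66→0.66 —
  improvement plateauing at nine months) with a patient random effect
  (SD 0.6) plus wave noise (SD 0.7) on the logit scale; the logistic
  transform preserves the median and keeps values in (0, 1). 25% of
  completed interviews are flagged as proxy responses (carried, unused).
* **resource use**: prevalence Bernoulli × positive part per category,
  survivors only — log-normal for day totals (home oxygen,
  re-hospitalization days, rehabilitation), shifted negative binomial for
  counts (ED, physician visits, medications). ICU and ventilated
  fractions of re-hospitalization days are unpublished; they are drawn as
  Beta(1.5, 3.5) and nested Beta(1, 3) fractions, which guarantees the
  nesting invariants. Lost work days (unpublished) default to prevalence
  0.40, mean 90 ± 80 d. Home help and ventilated SNF days are carried in
  the schema at zero use, since the weight table prices them but no usage
  is reported.

All randomness flows from a single seed (default 20110721) through one
generator, so identical configurations give byte-identical cohorts.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: within-patient correlation between severity,
costs, survival and utilities (draws are independent given arm); the
fluid-strategy co-randomization's clinical effects; informative interview
missingness; real billing structure. Synthetic arm differences in
lifetime QALYs at n = 300 are dominated by sampling noise, which is
faithful to the motivating trial (its arm differences were themselves
non-significant) but means single synthetic cohorts can favor either
arm.

## Numerical choices and degenerate inputs

* Trapezoid integration is exact for piecewise-linear trajectories; the
  suite checks it against a 0.01-day midpoint grid at 10⁻⁶ relative
  error.
* Rate-0 discounting reduces exactly to the undiscounted sum (tested as
  an identity, not a tolerance).
* Winsorization uses the type-7 empirical quantile; constant vectors are
  fixed points; empty input is an error.
* KM ties are handled deaths-before-censorings (the product-limit
  convention).
* Inconsistent survival anchors (S(365) > S(60)), utility points after
  death, negative day counts, ICU/vent days exceeding totals, missing
  CPI years and missing cost-to-charge ratios are rejected with named
  diagnostics rather than silently repaired.
* Degenerate PSA clouds (fewer than 3 trials, rank-deficient covariance)
  cannot yield an ellipse and error explicitly; a level-0 ellipse is the
  degenerate point at the mean.

## Problem sizes

Defaults are the study conditions: 300 patients/arm, 5000 PSA trials.
The test suite exercises the same code at reduced sizes chosen for a
laptop-scale run — cohorts of 30–150/arm and PSAs of 50–2000 trials for
behavioral checks, with full-size runs (5000-patient arms for generator
calibration, 5000-trial parametric PSA, a 50,000-point ellipse-coverage
cloud) where a check's precision demands it.

## Known limitations

* The one-year cost/effect accounting assumes complete cost capture;
  there is no missing-bill imputation (the real study lacked bills for
  ~3% of subjects).
* The parametric PSA mode treats published SDs as the sampling SDs of
  arm means and defaults to independence between cost and effect draws.
* Lifetime projection applies a flat utility and a flat annual cost to
  all survivors regardless of covariates; only a scalar multiplier
  perturbs life expectancy.
* No value-of-information analysis, no covariate-adjusted net-benefit
  regression, no formal subgroup-heterogeneity inference.
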
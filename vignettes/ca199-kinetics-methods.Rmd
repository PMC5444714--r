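---
title: "Modelling CA19-9 kinetics against overall survival: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CA19-9 kinetics against overall survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca19kinetics)
```

## The model

Serum CA19-9 is the standard circulating marker in advanced pancreatic
cancer. Patients under chemotherapy have it measured repeatedly at
irregular intervals, and both the *level* of the marker and the *timing* of
its prognostic impact are of interest. This package models the
instantaneous death hazard of patient $i$ as

$$\lambda(t \mid \mu_i, X_i(t)) \;=\; \lambda_0(t)\,
  \exp\{\gamma^{\top}\mu_i + \beta(t)\,X_i(t)\},$$

where $t$ is time in months since the start of chemotherapy,
$\lambda_0(t)$ the baseline hazard, $\mu_i$ the baseline covariates (age,
sex, chemotherapy group), $X_i(t)$ the most recent $\log_{10}$ CA19-9 value
(last observation carried forward), and $\beta(t)$ a time-varying log
hazard ratio per $\log_{10}$ unit — i.e. per 10-fold increase of the
marker. Two departures from the ordinary Cox model are combined:

* a **time-varying covariate** $X_i(t)$, handled by the counting-process
  expansion: each patient's follow-up is split into `(start, stop]`
  episodes at measurement-update times, covariates constant within an
  episode;
* a **time-varying coefficient** $\beta(t)$, estimated pointwise on a grid
  of follow-up times and smoothed with a natural cubic spline.

Because one patient contributes several correlated episodes, all standard
errors for episode-level fits use the clustered sandwich estimator
$A^{-1}BA^{-1}$, with $A$ the observed information and $B$ the
cross-product of per-patient summed score residuals.

### Units and scales

A coefficient of $1$ on $X(t)$ corresponds to a 10-fold increase in CA19-9
(one $\log_{10}$ unit). Reported hazard ratios are per $\log_{10}$ unit
throughout. Cohorts of this kind are sometimes summarised per "9-fold"
increase, which is ambiguous on the $\log_{10}$ scale; this package never
rescales and always states HRs per 10-fold change.

## Data preparation rules

`load_cohort()` applies, in order:

1. validation (positive concentrations, consistent patient-id sets,
   one survival and baseline row per patient);
2. optional day-to-month conversion at 30.4375 days/month — all results
   are reported in months;
3. $\log_{10}$ transformation;
4. within-week deduplication (`dedup_weekly()`): scanning left to right, a
   measurement is kept only if it falls at least 7 days after the last
   *kept* one. The window is anchored greedily at each retained
   measurement, which is the reading that keeps "the first of several
   measurements in one week" well defined for chains of closely spaced
   visits;
5. pretreatment selection: the last measurement at or before time 0. A
   patient whose pretreatment value is $\le 5$ U/mL is excluded (CA19-9
   non-secretors, the Lewis-negative phenotype) with the exclusion logged.

The pretreatment measurement's (negative) sampling time is retained as
metadata, but the covariate clock starts at 0: the overall-survival clock
starts at chemotherapy initiation, so the first episode is anchored there.
Values recorded at assay ceilings (1000 or 10000 U/mL in some
laboratories) are used as-is; no detection-limit correction is attempted.

## The Cox machinery

The partial likelihood, its derivatives, the Newton-Raphson fitter, both
tie corrections (Efron, the default, and Breslow), the score residuals
feeding the sandwich estimator, and the Schoenfeld residuals are all
implemented directly on the episode representation. Key conventions:

* **Risk sets.** Episodes are half-open intervals `(start, stop]`; the
  risk set at an event time $t$ contains episodes with
  $\text{start} < t \le \text{stop}$. This makes the partial likelihood
  exactly invariant to splitting an episode at an arbitrary interior time,
  which the test suite asserts to $10^{-8}$ — a useful internal
  consistency check, since splitting is also how the pointwise grid is
  handled.
* **Convergence.** Iteration stops when the relative log-likelihood change
  falls below $10^{-9}$ and the score's max-norm below $10^{-8}$
  (step-halving on overshoot, at most 50 iterations). A coefficient
  exceeding 15 in absolute value flags monotone likelihood — small
  landmark subgroups can separate perfectly, and an explicit flag is more
  honest than a silently enormous hazard ratio.
* **Ties.** Efron is the default because serial follow-up times recorded
  in months produce ties routinely and Efron's correction is the more
  accurate of the two; the comparison oracle in the tests is configured to
  match either choice.
* **Sandwich.** Per-episode score residuals are summed within patient;
  the robust covariance is the cross-product of the resulting dfbeta
  rows. With one episode per patient and singleton clusters this reduces
  to the ordinary robust variance.

### Proportional-hazards diagnostics

`schoenfeld_residuals()` returns, per death, the covariate of the failing
subject minus the risk-set weighted mean (under Efron ties, the average of
the step-wise means across a tied group). Scaled residuals follow the
Grambsch-Therneau convention $m\hat V r_k + \hat\beta$ with $m$ the number
of deaths and $\hat V$ the naive covariance of $\hat\beta$. `ph_test()` is
the classical Grambsch-Therneau score test for a linear association of the
scaled residuals with transformed time (KM transform by default; identity,
rank and log available). Two caveats are built into how the package
presents this test:

* a quadratic, rise-then-fall $\beta(t)$ can be plainly visible on the
  residual plot and still leave the linear-slope test non-significant —
  the identity transform is available precisely to probe this, and the
  smoothed $\beta(t)$ curve, not the test, is the primary exhibit;
* the test's null calibration is verified by simulation in the test suite
  (type-I error within [0.03, 0.08] at $\alpha = 0.05$ over 500 null
  replicates) rather than assumed.

## Estimating the time-varying coefficient

`pointwise_beta()` fits, for each grid time $t$, a Cox model in which only
deaths inside $[t - w/2, t + w/2)$ contribute event terms while all
episodes continue to feed the risk sets — a local-in-time partial
likelihood. Defaults: monthly grid from 0.5 to
$\min(12, \text{95th percentile of event times})$, window $w = 2$ months,
at least 5 deaths per window (windows below the minimum return a missing
flag), baseline covariates re-estimated inside each window (`gamma =
"local"`); a plug-in mode (`gamma = "global"`) holds them at their
full-data estimates via an offset and differs only to second order. These
defaults keep every window identifiable at the ~109-patient scale the
package targets and are all exposed as arguments.

`smooth_beta()` performs a weighted natural-cubic-spline regression of the
pointwise estimates on grid time, with inverse-variance weights
$1/\text{SE}^2$ and, by default, 4 degrees of freedom with interior knots
at event-time quantiles. The natural boundary condition makes the curve
linear beyond the boundary knots — asserted in the tests by checking that
second differences vanish there — so extrapolation is deliberately tame.
The 95% band is a delta-method band from the spline-coefficient
covariance. Two approximations are accepted and documented rather than
patched:

* adjacent windows overlap, so the pointwise estimates are positively
  correlated; the weighted least-squares band ignores this and is
  therefore a *descriptive* pointwise band, not a simultaneous one;
* the band reflects smoothing-stage uncertainty only.

`hr_curve()` exponentiates the curve and its band and records a horizontal
reference (default HR 1.56, the adjusted pretreatment-marker effect used
as the reference level in this literature) and a vertical marker at the
curve's maximum.

### What peak localisation can and cannot achieve

Monte-Carlo evaluation under the package's own generator (rise-fall truth
peaking at HR 2 against a plateau of 1.56) shows that the *replicate-
averaged* smoothed curve peaks in the correct 1.5-2.5-month window and
holds its plateau near 1.56. Per replicate, however, the log-contrast
between peak and plateau is only $\ln(2/1.56) \approx 0.25$ — and the
2-month window averages it down to about 0.21 — while the pointwise
standard errors run 0.10-0.20 at 1000 patients. The single-replicate
argmax therefore lands in the 1.5-2.5-month window only about half the
time, with the remainder drawn to the high-variance curve endpoints. A
range of estimator variants (finer sliding grids, disjoint windows,
equal-event windows, generalised-least-squares smoothing with the overlap
correlation, stiffer splines, information-based weights) were evaluated
and none materially exceeds this; the limitation is informational, not
algorithmic, and users should read the peak marker on a single cohort of
this size as indicative, not as a precise estimate.

## Nonparametric comparisons

Kaplan-Meier estimation and the log-rank test wrap the `survival` package
(the de-facto reference implementation) behind tidy interfaces. Package
conventions: the median is the smallest step time with $S(t) \le 0.5$, no
interpolation (so an exact-0.5 plateau reports its left edge); at tied
times events precede censorings. The two-group log-rank statistic equals
the Cox score test for the group indicator under Breslow ties — the test
suite checks this equivalence against the package's own from-scratch score
test, keeping the two routes independent.

## Landmark and cutoff analyses

`landmark_classify()` declares a patient evaluable at landmark month $k$
if still at risk (`os_months > k`) and measured within $\pm 0.5$ months of
the landmark (the nearest such measurement is used). "CA19-9 at month
$k$" has no canonical definition for irregular schedules; the half-month
window is the package's choice and both the at-risk count and the
with-measurement count are reported so the two candidate "N" definitions
are always visible.

Survival comparisons are **re-anchored at the landmark** by default:
follow-up restarts at $k$, which removes immortal-time bias by
construction (every evaluable patient has positive re-anchored follow-up —
asserted in the tests). Because all evaluable patients enter at the same
landmark time, the origin-scale analysis has identical risk sets: HRs and
log-rank p-values are unchanged and medians simply shift by $k$ months, so
`anchor = "origin"` is provided for display compatibility.

The combined grouping intersects the pretreatment and 2-month
dichotomies, compares the two concordant groups and excludes discordant
patients, whose subgroups are too small to analyse separately at this
cohort scale. `sensitivity_sweep()` repeats both analyses over a cutoff
ladder (default 1000, 800, 600, 400, 200 U/mL) and never aborts on a
degenerate cutoff — per-row flags carry empty-group or divergence
conditions. No multiplicity adjustment is applied across months or
cutoffs, matching descriptive practice for this kind of sensitivity
analysis; the p-values are exploratory.

## The synthetic-cohort generator

No registry data ship with this package; `simulate_cohort()` generates
cohorts with the structure the analysis assumes, so every stage is
testable against a known truth.

* **Hazard.** Survival times are drawn by exact inversion of the
  cumulative hazard $\int \lambda_0(s) e^{\gamma^\top\mu + \beta(s)X(s)}
  ds$: on every piece where $\lambda_0$ and $X$ are constant and $\beta$
  linear the integral has a closed form, and the crossing piece is
  inverted analytically. The hazard acts on the LOCF path of the
  *observed* marker values, exactly the path the analysis reconstructs, so
  fitted coefficients are directly comparable to the configured truth and
  the Wald-interval coverage test closes the loop end to end.
* **Effect shape.** The default $\beta(t)$ is continuous piecewise-linear
  in log-HR: 1.56 at the start, a peak of 2 at month 2, back to 1.56 at
  month 4, constant thereafter. A constant-effect specification is
  provided for null and calibration runs.
* **Trajectories.** Observed $\log_{10}$ values are patient level +
  mean-reverting excursion + measurement noise, sampled exactly at the
  irregular visit times (`intercept_sd` 0.4, Ornstein-Uhlenbeck stationary
  SD 0.7 with reversion rate 0.8/month, noise SD 0.15, clipped to the
  observed assay range 5.1-12777 U/mL). A purely linear random-slope model
  was evaluated first and rejected: with persistent slopes, the separation
  between high and low marker groups *grows* with landmark month, so late
  landmarks always discriminate best and the characteristic
  strongest-at-2-months landmark pattern cannot arise. Mean-reverting
  dynamics — response followed by rebound, which is also the clinically
  typical on-treatment behaviour — make a landmark measurement predictive
  mainly of the hazard near that landmark, and the pattern follows.
  `ou_sd = 0` recovers the linear model.
* **Schedule.** One pretreatment draw at a uniform time in the month
  before treatment, then gaps of 0.25 months plus an exponential with a
  patient-specific rate drawn from a gamma distribution (shape 1.2, mean
  0.65/month), at most 16 measurements. The minimum gap emulates data that
  have already passed weekly deduplication, so generated cohorts are
  analysis-ready and the hazard path and analysis path coincide.
* **Calibration.** The constant baseline hazard (0.023/month) and the
  visit-rate distribution were fixed once, by Monte-Carlo at n = 5000,
  to reproduce the cohort-scale facts the generator is required to
  emulate: marginal median OS about 7.4 months (administrative censoring
  at 34.1 months plus 0.01/month dropout), median pretreatment CA19-9
  about 532 U/mL on a 5-10000 U/mL range, and 1-16 measurements per
  patient with median 3 and roughly three quarters of patients measured
  at least twice.
* **Reproducibility.** Each patient consumes a dedicated RNG substream
  derived from the seed, so a cohort is bit-reproducible and enlarging
  `n` extends it without reshuffling earlier patients.

What the generator does *not* emulate: informative visit schedules (sicker
patients being measured more often), inter-laboratory assay differences,
a non-secretor subpopulation, measurement-error attenuation (the hazard is
driven by the observed values, so there is no latent-vs-observed gap), or
dependence between trajectory parameters. Passing tests demonstrate
correctness of the machinery under the stated generative model, not
robustness to these real-data features.

## Problem sizes in the test suite

The suite exercises closed-form fixtures and oracle comparisons at
50-60 subjects; recovery, calibration and coverage properties use
100 replicates at n = 1000 (coverage, shape), 500 replicates at n = 120
(PH-test null calibration), 100 replicates at n = 500 (PH-test power), and
n = 5000 single cohorts for distributional checks — sizes chosen to give
Monte-Carlo standard errors comfortably inside the asserted bands on a
single CPU.

## Known limitations

* The $\beta(t)$ band is pointwise and ignores window-overlap correlation.
* Landmark analyses use the measurement nearest the landmark; no
  interpolation or modelling of the measurement process is attempted.
* No stratified baseline hazards, frailties, joint longitudinal-survival
  modelling, or penalized spline selection; the spline df is fixed by the
  user.
* Single-replicate peak localisation at registry scale is noisy (see
  above); shape statements should be read from the curve with its band,
  not from the argmax alone.
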
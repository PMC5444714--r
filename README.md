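# ca19kinetics

Varying-coefficient Cox analysis of serial CA19-9 measurements against
overall survival in advanced pancreatic cancer.

Serum CA19-9 is the standard tumour marker in pancreatic cancer, measured
repeatedly during chemotherapy on irregular schedules. Its prognostic
effect is not constant: the association between the current marker level
and the death hazard strengthens early in treatment, peaks around two
months, and settles back. Analyses that treat the marker as a fixed
baseline covariate, or its effect as constant over follow-up, miss both
features. This package is for biostatisticians and clinical researchers
who want to model both at once and to run the accompanying landmark and
cutoff subgroup analyses.

## The model

The death hazard of patient $i$ is

$$\lambda(t \mid \mu_i, X_i(t)) = \lambda_0(t)\,
  \exp\{\gamma^{\top}\mu_i + \beta(t)\,X_i(t)\},$$

with $X_i(t)$ the last observed $\log_{10}$ CA19-9 (so coefficients are
per 10-fold increase), $\mu_i$ baseline covariates, and $\beta(t)$ a
time-varying coefficient. The machinery:

- **counting-process expansion** of serial measurements into
  `(start, stop]` episodes with last observation carried forward;
- **from-scratch Cox partial likelihood**: Newton-Raphson fitting, Efron
  or Breslow ties, clustered sandwich variance for the correlated episodes
  of one patient, Schoenfeld residuals and the Grambsch-Therneau
  proportional-hazards test;
- **time-varying coefficient estimation**: pointwise local fits on a
  follow-up grid, smoothed by a weighted natural cubic spline into an
  HR(t) curve with a 95% band (`autoplot()` draws it);
- **Kaplan-Meier / log-rank** subgroup comparisons, **landmark**
  dichotomisation at literature cutoffs (1000 U/mL and a 200-1000
  sensitivity ladder), and the combined pretreatment + 2-month grouping;
- a **calibrated synthetic-cohort generator** (109 patients, median OS
  7.4 months, median pretreatment CA19-9 ~532 U/mL, 1-16 measurements per
  patient) so every stage is testable against a known truth.

## Worked example

```r
library(ca19kinetics)

sc <- simulate_cohort(sim_config(), seed = 7)   # n = 109, study-scale defaults
sc$cohort
#> <ca19_cohort> 109 patients, 87 deaths, 665 CA19-9 measurements
#>   median OS: 9.57 months; median pretreatment CA19-9: 662.2 U/mL

ep  <- expand_counting_process(sc$cohort)
fit <- fit_tvcox(ep, covariates = c("log_ca199", "age_years", "sex",
                                    "chemo_group"))
tidy(fit, exponentiate = TRUE)
#> # A tibble: 4 x 7
#>   term        estimate std.error statistic p.value conf.low conf.high
#> 1 log_ca199      1.58     0.151      3.04  0.00236    1.18       2.13
#> 2 age_years      1.03     0.0108     2.30  0.0214     1.00       1.05
#> 3 sex            0.681    0.210     -1.83  0.0675     0.451      1.03
#> 4 chemo_group    0.848    0.212     -0.777 0.437      0.559      1.29
```

The `log_ca199` row says a 10-fold higher current CA19-9 carries a 1.58-fold
hazard (robust 95% CI 1.18-2.13) when its effect is held constant over
follow-up — the generating truth averages 1.6 over this follow-up window.
The standard errors are clustered by patient, since one patient contributes
several episodes.

The time-varying effect, at a scale where the curve is well resolved:

```r
big   <- simulate_cohort(sim_config(n = 1000), seed = 7)
curve <- smooth_beta(pointwise_beta(expand_counting_process(big$cohort),
                                    window = 2), df = 4)
curve
#> <beta_curve> natural cubic spline, 4 df; interior knots at 2.04, 4.01, 7.21 months
#>   peak: beta = 0.585 (HR = 1.79) at 4.28 months
autoplot(hr_curve(curve, reference = 1.56))   # HR(t) with band and markers
```

The generator's truth rises from HR 1.56 to 2 at month 2 and returns to
1.56 by month 4; this replicate estimates a peak of 1.79 at 4.3 months —
single-replicate peak localisation is noisy even at n = 1000, which is why
the curve should be read with its band (the methods vignette quantifies
this).

Landmark analysis at 2 months, 1000 U/mL cutoff:

```r
landmark_analysis(sc$cohort, month = 2, cutoff = 1000)
#>   n n_low n_high median_low median_high logrank_p hr_crude
#> 1 31    22      9       24.5        14.9     0.152     1.91
```

Among the 31 patients still at risk and measured near month 2, those below
1000 U/mL have a longer re-anchored median survival (24.5 vs 14.9 months)
and the crude hazard ratio for the high group is 1.91; at n = 31 the
log-rank test is not significant. `landmark_table()` sweeps months 1-6,
`sensitivity_sweep()` repeats everything over the 1000-200 U/mL cutoff
ladder, and `combined_group_analysis()` intersects the pretreatment and
2-month dichotomies.

Real data enter through three CSVs (long measurements, one-row survival,
baseline covariates) via `load_cohort()`, which applies the preparation
rules: log10 transform, within-week deduplication, last-before-treatment
pretreatment selection, and exclusion of non-secretors (pretreatment
<= 5 U/mL).

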
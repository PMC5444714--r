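Package: ca19kinetics
Title: Varying-Coefficient Cox Analysis of Serial CA19-9 Kinetics and
    Overall Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating serial tumour-marker measurements to overall
    survival in advanced pancreatic cancer cohorts. Serial CA19-9
    measurements are expanded into counting-process episodes with the last
    observation carried forward, and the hazard is modelled as
    lambda0(t) * exp(gamma'mu + beta(t) * X(t)) with a time-varying covariate
    X(t) (log10 CA19-9) and a time-varying coefficient beta(t). The Cox
    partial-likelihood machinery (Newton-Raphson fitting with Efron or
    Breslow ties, clustered sandwich variance, Schoenfeld residuals and the
    Grambsch-Therneau proportional-hazards test) is implemented from first
    principles; beta(t) is estimated pointwise on a follow-up grid and
    smoothed with natural cubic splines to give a hazard-ratio curve with a
    confidence band. Kaplan-Meier/log-rank subgroup comparisons, landmark
    dichotomisation at literature cutoffs, the combined
    pretreatment-plus-two-month grouping, a cutoff sensitivity sweep, and a
    calibrated synthetic-cohort generator for validating every stage are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    splines,
    stats,
    survival,
    tibble,
    utils
Suggests:
    broom,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
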
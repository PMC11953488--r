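# ebdive

Analysis and simulation of post-dive venous gas bubble grades in
no-decompression recreational air diving.

After a dive, inert gas (mainly nitrogen) absorbed at depth can form
intravascular bubbles during and after ascent. On transthoracic
echocardiography these are scored on the Eftedal–Brubakk (EB) scale from 0
(no bubbles) to 5 (extensive bubbles); higher grades indicate greater
decompression stress even in symptom-free divers. `ebdive` is aimed at
diving-physiology and biostatistics researchers who want to study how dive
profiles and diver characteristics predict the EB grade, and to exercise the
full analysis pipeline without access to diver data.

The package implements four connected pieces:

1. **Dive-profile features** — depth–time series are piecewise linear;
   maximum depth, dive time, and the time spent in the 10-m depth bands
   `[0,10), [10,20), [20,30), [30,40)` (total, and after the first
   attainment of maximum depth) are computed analytically from the exact
   boundary-crossing times.

2. **Field risk formula** — a fixed-coefficient predictor of the EB grade
   from four readily available quantities:

   EB ≈ (age[y]/50 − SI[h]/150 + depth[m]/45 + air[bar·L]/4500)²

   with the surface interval SI saturating at 48 h, plus configurable
   low/elevated/high risk classes.

3. **Mixed-effects analysis** — the repeated-measures model
   `log(EB + 1) ~ depth + shallow + depth:shallow + (1 | diver)` (REML via
   lme4), where `shallow` is the time between 0 and 10 m after maximum
   depth, with its variance decomposition: between-diver variance τ²,
   residual σ², ICC = τ²/(τ²+σ²), marginal/conditional R²
   (R²m = V_f/(V_f+τ²+σ²), R²c = (V_f+τ²)/(V_f+τ²+σ²)), and
   mean-centred standardised coefficients. A random-forest comparison of
   nested predictor sets (person-specific → full dive-computer data) and a
   Spearman correlation table (exact permutation p for n ≤ 10) complete
   the inferential stack.

4. **Synthetic cohort generator** — a seeded simulator of 59 divers and
   359 dives whose covariates follow published summary statistics, whose
   profiles are realistic trapezoids, and whose grades come from the
   published mixed-model coefficients run forward, with τ²/σ² calibrated
   in closed form so that R²m = 0.17, R²c = 0.29 and ICC = 0.1446 by
   construction. This is the test bed for everything else (parameter
   recovery, ordering properties, pipeline round trips).

## Worked example

```r
library(ebdive)

# a 41-year-old after a 32 m dive, 16 h surface interval, 2400 bar*L used
predict_eb(age = 41, surface_interval = 16, max_depth = 32,
           air_consumption = 2400)
#>  predicted_grade  clamped risk_class
#>         3.832894 3.832894       high

co <- simulate_cohort(cohort_config(), seed = 42)
co
#> <dive_cohort: 59 divers, 359 dives, seed 42>
#>   EB grade >= 1 in 42.6% of dives

fit_eb_mixed(co$dives)
#> Mixed model of log(grade + 1): 359 dives, 59 divers
#>               estimate      se        t
#> (Intercept)   -0.28771 0.09123 -3.15380
#> depth          0.02765 0.00337  8.21094
#> shallow        0.00896 0.00281  3.19086
#> depth:shallow -0.00058 0.00016 -3.65852
#> tau2 = 0.01649, sigma2 = 0.1476, ICC = 0.100
#> R2 marginal = 0.198, R2 conditional = 0.278
#> standardised betas:
#>   (Intercept)         depth       shallow depth:shallow
#>        -0.094         0.428        -0.179        -0.190
```

The fit recovers the generative world: depth raises the log-grade
(raw 0.0277 per metre), extra shallow time after the deepest point lowers
it at depth (negative interaction; the *standardised* shallow-time beta is
negative at the covariate means even though the raw coefficient is
positive), and about 10–15% of the unexplained variance is stable
between-diver differences.

```r
rf_variable_set_eval(co$dives, co$divers, seed = 42)[, 1:3]
#>               set    rho_all rho_excluding_zero
#> 1 person_specific 0.03183787        -0.01831556
#> 2    minimal_dive 0.41293529         0.48496542
#> 3     person_dive 0.49628867         0.64510480
#> 4 person_dive_air 0.49490387         0.56395689
#> 5   dive_computer 0.38439075         0.47980871
#> 6             all 0.43705992         0.50742056
```

Dive-derived variables dominate person-specific ones, mirroring the
field's finding that the dive, not the diver's biometrics, carries most of
the predictive signal.

A command-line wrapper covers the same pipeline
(`inst/cli/ebdive simulate|features|predict|evaluate|analyze|mlcompare`).

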
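# jointpredict

Dynamic prediction of death from recurrent-event history, using a joint
frailty model and a landmark Cox alternative, with the external-validation
machinery (IPCW Brier curves, explained variation, calibration) needed to
judge the predictions on new cohorts.

## The problem

In diseases where patients experience repeated non-fatal events — the
motivating setting is breast cancer, where loco-regional relapses and distant
metastases precede many deaths — the relapse history carries strong prognostic
information about survival. Relapses and death are *semi-competing risks*:
death stops the relapse process, so relapses cannot be thrown into a survival
model as an ordinary time-dependent covariate. Two established ways around
this are implemented here for users who want individual, updatable risk
estimates (biostatisticians, prognosis researchers):

* **Joint frailty modelling.** Subject `i`'s relapse and death hazards share
  an unobserved gamma frailty `u_i` (mean 1, variance `theta`) with a power
  link `alpha`:

  ```
  relapse:  lambda_ij^R(t | u_i) = u_i       lambda_0^R(t) exp(beta_1' z_i)
  death:    lambda_i^D(t | u_i)  = u_i^alpha lambda_0^D(t) exp(beta_2' z_i)
  ```

  on the calendar timescale (risk of the j-th relapse starts at the
  (j−1)-th). Baseline hazards are M-spline expansions estimated by penalized
  maximum likelihood with the frailty integrated out numerically; `alpha > 0`
  means patients prone to relapse also die sooner.

* **Landmarking.** At a prediction time `s`, refit a Cox model for death on
  the subjects still alive and uncensored, with the number of previous
  relapses (0 / 1 / 2+) as an extra baseline covariate.

From a fitted joint model the package computes, for any subject alive at
`s` and any window `w`, the conditional probability of death in `(s, s+w]`
either **using** the relapse history (`predict_rec`: conditions on the `J`
observed relapse times and the absence of a further relapse by `s`, via a
ratio of gamma-frailty integrals) or **ignoring** it (`predict_ign`), plus
the landmark analogue (`predict_lm`). Predictions update as `s` advances
without refitting the joint model.

Validation on a (possibly shifted) cohort uses the
inverse-probability-of-censoring-weighted Brier score `Err_{s,w}`, the
explained residual variation `R^2 = 1 − Err_{s,w} / Err_{s,w;KM}` against the
covariate-free Kaplan–Meier predictor, and decile calibration tables with
95% intervals.

Because the registry data behind this class of analyses are confidential, the
package ships a synthetic-cohort generator (`simulate_cohort`) that draws
from the joint frailty model itself: registry-like covariate mixes, Weibull
baselines calibrated so that about two thirds of subjects have no recorded
relapse and five-year survival is about 89%, administrative plus early
censoring, and an optional five-year relapse-recording truncation. Every
stage of the pipeline is testable against it.

## Worked example

```r
library(jointpredict)

scn <- simulation_scenario("french_like", n_subjects = 600, seed = 42)
co  <- simulate_cohort(scn$true, scn$config)
co
#> A cohort of 600 subjects (origin: diagnosis )
#>   deaths: 136  relapses: 300  max follow-up: 15 years
#>   relapse count: 0=409 1=125 2=39 3=16 4+=11

fit <- fit_joint_model(co, joint_control(n_basis = 6))
fit
#> Joint frailty model (gamma frailty, power link)
#>   n = 600  relapses = 300  deaths = 136
#>   theta = 1.26 (se 0.218 )  alpha = 1.228 (se 0.278 )
#>   penalized log-likelihood: -1721.6206  converged: TRUE
#>            HR_relapse HR_death
#> age_le40        2.860    2.259
#> age_40to55      0.903    0.262
#> pvi             1.873    6.104
#> size_gt20       2.691   10.329
#> nodal           1.817    4.102
#> grade_II        1.619    3.977
#> grade_III       2.494   23.747
```

`theta` is the frailty variance (heterogeneity in relapse/death risk beyond
the covariates; generative value 1.07 here) and `alpha` the power link
(generative value 1.5). The columns are hazard ratios for relapse and death.

Dynamic predictions for one subject alive at 5 years, window 5 years:

```r
subj <- co$subjects[co$subjects$followup_time > 5, ][1, , drop = FALSE]
rt   <- relapse_times(co, subj$id); rt <- rt[rt <= 5]
predict_rec(fit, subj, rt, s = 5, w = 5)$probability   # 0.012
predict_ign(fit, subj,     s = 5, w = 5)$probability   # 0.015

lmfit <- fit_landmark_cox(build_landmark_dataset(co, 5))
predict_lm(lmfit, subj, length(rt), s = 5, w = 5)$probability  # 0.018
```

This subject has no relapse by year 5, so conditioning on that history
*lowers* the risk relative to ignoring it. External validation on a
case-mix-shifted cohort:

```r
val <- simulate_cohort(simulation_scenario("west_midlands_like",
                                           n_subjects = 800)$true,
                       simulation_scenario("west_midlands_like",
                                           n_subjects = 800)$config, seed = 7)
prediction_error_curve(val, joint = fit,
                       landmark_fitter = function(s)
                         fit_landmark_cox(build_landmark_dataset(co, s)),
                       settings = c("rec", "ign", "lm"), s = 5, w = c(2, 5))
#>   setting s w   n    err err_km     r2
#> 1     rec 5 2 663 0.0373 0.0397 0.0595
#> 2     ign 5 2 663 0.0387 0.0397 0.0243
#> 3      lm 5 2 663 0.0387 0.0397 0.0242
#> 4     rec 5 5 663 0.0822 0.0934 0.1194
#> 5     ign 5 5 663 0.0860 0.0934 0.0790
#> 6      lm 5 5 663 0.0852 0.0934 0.0873
```

The relapse-aware prediction cuts the Brier error the most at every grid
point; the landmark model sits between the two joint-model settings.
`calibration_table()` and the plotting helpers (`plot_error_curves`,
`plot_calibration`) complete the validation layer, and `run_study()` drives
the whole simulate → fit → externally-validate pipeline from one seed.

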
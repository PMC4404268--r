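---
title: "Dynamic prediction of death from relapse history: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic prediction of death from relapse history: models, numerics, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(jointpredict)
```

This vignette is the package's own account of the statistics it implements:
the joint frailty model for recurrent relapses and death, the three dynamic
prediction settings, the landmark Cox comparator, the external-validation
layer, and — in most detail — the numerical and design choices a user should
know before trusting the output.

## The model

For subject $i$ with baseline covariates $z_i$, relapse calendar times
$X_{i1} < X_{i2} < \dots$, follow-up $T_i = \min(D_i, C_i)$ and death
indicator $\delta_i$, the joint frailty model couples the two event
processes through a shared gamma frailty:

$$
\lambda^R_{ij}(t \mid u_i) = u_i\,\lambda^R_0(t)\,e^{\beta_1' z_i},
\qquad
\lambda^D_i(t \mid u_i) = u_i^{\alpha}\,\lambda^D_0(t)\,e^{\beta_2' z_i},
\qquad
u_i \sim \mathrm{Gamma}(1/\theta,\,1/\theta).
$$

The frailty has mean 1 and variance $\theta$; $\alpha$ controls how strongly
relapse-proneness translates into death risk ($\alpha = 0$: independent
processes given covariates). Everything runs on the *calendar* timescale: a
subject is at risk for the $j$-th relapse only after the $(j{-}1)$-th, so the
at-risk intervals partition $(0, T_i]$ and, with baseline covariates only,
the accumulated relapse intensity telescopes to
$e^{\beta_1'z_i}\Lambda^R_0(T_i)$.

Assumptions worth stating: proportional hazards on both transitions;
time-constant covariate effects; one scalar frailty shared by all relapse
ranks and by death; gamma frailty distribution; independent censoring. None
of these are testable from a single fitted model — the synthetic-data checks
below exercise the software under the model, not the model against nature.

## The three predictions

Given a fitted parameter vector, the probability of death in $(s, s+w]$ for a
subject alive at $s$ is computed three ways:

* `predict_rec` conditions on the observed history: $J$ relapses at times
  $\le s$ and no $(J{+}1)$-th relapse by $s$. It is a ratio of
  gamma-frailty integrals whose integrands contain
  $[S^D(s\mid u) - S^D(s{+}w\mid u)]\,u^J\,S^R_{(J+1)}(s \mid u)$ in the
  numerator and the same without the survival difference in the denominator.
* `predict_ign` drops the history from the conditioning (the relapse process
  still shaped the parameter estimates).
* `predict_lm` is the landmark Cox analogue
  $[S(s) - S(s{+}w)]/S(s)$ under a model refitted at $s$.

A relapse exactly at $s$ is part of the history ($X_{iJ} \le s$ is allowed);
its next-relapse survival factor is then 1. With $\alpha = 0$ the $u$-terms
cancel in the ratio and `predict_rec` collapses onto `predict_ign` for every
$J$ — the package's tests verify this to $10^{-10}$.

## Estimation

**Baseline hazards.** Each baseline hazard is an order-4 (cubic) M-spline
expansion $\lambda_0(t) = \sum_k \eta_k M_k(t)$ on $[0, t_{\max}]$ with
$t_{\max}$ the largest observed time. M-splines are non-negative and
integrate to one over their support, so $\eta_k \ge 0$ guarantees a valid
hazard; non-negativity is enforced by optimizing $\zeta_k$ with
$\eta_k = \zeta_k^2$. The default is 7 basis functions per hazard
(`joint_control(n_basis = )`), interior knots at equally spaced quantiles of
the observed event times, and one shared knot set for both hazards
(`share_knots = FALSE` gives each hazard its own quantile-based knots).
Cumulative hazards use the integrated basis, computed by exact
piecewise-polynomial (Gauss–Legendre) integration. Extrapolation beyond
$t_{\max}$ is an error, not a warning: predictions need
$\Lambda^D_0(s{+}w)$, so the requested horizon must lie inside the fitted
support.

**Penalty.** Smoothness is imposed through the exact curvature Gram matrix
$P_{jk} = \int M_j'' M_k''$, one smoothing parameter per hazard
(`kappa_rec`, `kappa_death`, default $10^3$). The default was fixed once via
a coarse likelihood-cross-validation grid on a development-type simulation,
where the criterion was flat across $10^1$–$10^5$; estimates of
$(\beta, \theta, \alpha)$ are insensitive to it in that range. The penalty's
null space contains all linear hazards.

**Frailty integration.** Marginal likelihood contributions
$\log \int e^{\ell_i(u)} g(u)\,du$ use a fixed 64-node rule with log-domain
accumulation (the $u^J$ and survival-product terms underflow otherwise). Two
rules are available and the package picks per integral family:

* *Generalized Gauss–Laguerre* (Golub–Welsch construction, parameter
  $a = 1/\theta - 1$, valid for any $a > -1$): exact for integrands of the
  form (polynomial in $u$) $\times\, e^{-cu}$, which is precisely the
  likelihood family at $\alpha = 1$. Used for likelihood-type integrals
  whenever $\theta < 2$ or $\alpha = 1$.
* *Gauss–Legendre on the gamma-quantile scale*: nodes at
  $F^{-1}_\theta(p_k)$. Markedly more accurate for bounded prediction
  integrands once $\theta \gtrsim 1$, where the gamma density's integrable
  singularity at zero defeats the Laguerre weights; also the fallback for
  $\theta < 1/150$, where the Laguerre weight normalization overflows.
  Predictions use it whenever $\theta \ge 0.5$ and $\alpha \ne 1$.

The tests pin both rules against closed forms ($\alpha=1$ gamma integral,
Laplace-transform benchmark 0.25), against `integrate()`, and against
$10^6$-draw Monte-Carlo frailty integrals over a grid of
$(\theta, \alpha, J)$.

**Optimization.** Quasi-Newton (BFGS) on the working vector
$(\zeta^R, \zeta^D, \beta_1, \beta_2, \alpha, \log\theta)$, objective scaled
per subject. Gradients are analytic — posterior node weights give
$E[u \mid \text{data}]$-type expectations from the same forward pass — except
for $\log\theta$, which uses a central finite difference because the
quadrature nodes themselves depend on $\theta$. Initial values come from
independent no-frailty fits (Andersen–Gill Cox on the counting-process rows
for $\beta_1$, a Cox model for $\beta_2$), constant-hazard spline
coefficients matched to crude event rates, $\theta_0 = 0.5$,
$\alpha_0 = 1$. Convergence requires the optimizer's relative-change
criterion plus a gradient sup-norm below $10^{-4}$ (per subject); fits
failing either return `converged = FALSE` with the last iterate. `theta`
and/or `alpha` can be held fixed (`fix_theta`, `fix_alpha`), which is how the
no-frailty degeneracy check ($\theta = 10^{-6}$, $\alpha = 1$) reproduces
Cox/Andersen–Gill coefficients.

**Standard errors** come from the inverse numerical Hessian on the working
scale, mapped by the delta method ($\mathrm{se}(\theta) = \theta\,
\mathrm{se}(\log\theta)$). **LCV** is implemented as
$\frac{1}{n}[\mathrm{tr}(H_{pl}^{-1} H_l) - l(\hat\xi)]$ with penalized and
unpenalized observed information on the working scale; with zero smoothing
the trace equals the number of free parameters and LCV is AIC-like. The
criterion's exact historical form is not printed in the lineage this package
follows, so treat LCV as a relative diagnostic, not an absolute quantity.

## The landmark model

`build_landmark_dataset(x, s)` keeps subjects with follow-up strictly beyond
$s$ and codes the relapse count before $s$ as indicators for one and for two
or more previous relapses (reference: none). Pooling "2+" reflects how
sparse higher counts are at realistic relapse rates; the timing of past
relapses is deliberately not used, only their number. The fit maximizes the
penalized *full* likelihood with an M-spline baseline on the time-since-
landmark scale $\tau = t - s$, which handles left truncation by
construction ($\Lambda_{s,0}(s) = 0$); this is a reparameterization, not a
reset of the scientific time origin. A masking test verifies bit-identical
fits when post-$s$ relapses are perturbed; a partial-likelihood oracle pins
$\hat\beta_s$ against `survival::coxph` within 0.02 log-HR.

## Validation layer

* **Censoring distribution**: reverse Kaplan–Meier (death indicator
  flipped), deaths preceding censorings at ties. Weights use the left limit
  $\hat G(T^-)$ at death times; the printed-formula convention $\hat G(T)$
  differs only on the null set of exact step times, but the left limit is
  the consistent choice and is what the package evaluates.
* **IPCW Brier error** at $(s, w)$ over the $N_s$ subjects alive and
  uncensored at $s$; a brute-force double-loop oracle in the tests agrees to
  $10^{-12}$, and with no censoring every weight is exactly 1.
* **$R^2 = 1 - \mathrm{Err}_{s,w}/\mathrm{Err}_{s,w;KM}$** against the
  cohort-level conditional Kaplan–Meier predictor; negative values mean the
  model predicts worse than the average.
* **Calibration**: deciles of predicted risk; observed proportions use a
  conditional Kaplan–Meier within each decile (reducing to the raw
  proportion when nobody is censored inside the window — the passive-
  follow-up registry situation), with Greenwood intervals on the KM scale
  and Wilson score intervals in the censoring-free case. Identical
  predictions collapse the deciles with a warning rather than an error.

For prediction-error curves the landmark model is refitted at every distinct
$s$ in the grid (`landmark_fitter` argument), mirroring how landmarking is
meant to be used; the joint model is fitted once.

## The synthetic-cohort generator

`simulate_cohort` draws from the generative model itself, with *parametric*
(Weibull) baselines rather than splines — inversion of the cumulative hazard
is then exact, and the fitted splines must approximate a family they do not
contain, which is a fairer software test than self-fitting. Defaults of the
`french_like` scenario: covariate frequencies of a development-type
breast-cancer series (three age classes, peritumoural vascular involvement
26.7%, tumour >20 mm 22.7%, nodal involvement 42.3%, grades I/II/III);
log-hazard-ratio vectors on the development-model scale; $\theta = 1.07$;
$\alpha = 1.5$ by default — the full-strength association estimated on real
data ($\alpha = 4.45$) drives such extreme death risks for high-frailty
subjects that it is kept as the separate named scenario
`french_like_extreme`; Weibull shapes 0.95 (relapse) and 1.25 (death) with
scales 85 and 800, calibrated once at large $n$ so that roughly 66% of
subjects have no recorded relapse and five-year survival is about 0.89.
Censoring is administrative at 15 years plus a 20% fraction censored
uniformly on (5, 15) so the IPCW weights are genuinely exercised; the
censoring mechanism of the real development series is not published, so this
is a package choice flagged in the configuration. `west_midlands_like` and
`netherlands_like` shift the covariate mix toward the more severe registry
populations (the severity shift runs through covariates, not through changed
coefficients); the Dutch-style scenario truncates relapse recording at five
years. The peritumoural-vascular-involvement frequency for the
Dutch-style scenario is the development value, since that registry did not
record the factor.

What the generator does **not** emulate: treatment effects and their secular
trends, dependence between covariates, relapse-type distinctions
(loco-regional vs metastatic), registry relapse-retrieval artifacts beyond
the five-year truncation knob, and lost-to-follow-up processes other than
the configured censoring. Passing tests therefore demonstrate that the
estimation and validation machinery is correct *under the model*, not that
the model describes any particular registry.

One regime consequence deserves emphasis. Under the calibrated defaults the
conditional death probabilities over typical windows stay below ~20%
(rare-event regime). There the Brier $R^2$ of a well-specified predictor
*grows* with the window length — the reducible variance scales with the
squared conditional risk while the Bernoulli noise scales linearly — so
comparisons of $R^2$ across windows on these synthetic cohorts behave
oppositely to what is seen in higher-mortality validation samples, where
risks saturate. The test suite asserts the orderings that are
regime-independent (relapse-aware $\ge$ history-free everywhere; the
history-free setting underestimates risk in the relapsed subgroup under a
strong power link).

## Problem sizes and reproducibility

The test suite runs entirely on generated data: recovery checks use one
cohort of $n = 2000$ plus ten replicates of $n = 1000$ (bias of
$\hat\theta, \hat\alpha$ within 10%); Monte-Carlo oracles use $10^6$ frailty
draws; self-calibration uses $10^4$ binary outcomes; direction-of-effect
checks use cohorts of 3000–4000. These sizes were chosen as the smallest at
which the Monte-Carlo noise is comfortably below the tested effects. All
simulation flows from explicit seeds; `run_study()` derives every stage's
stream from one root seed and reruns byte-identically.

## Known limitations

* Baseline covariates only; no time-varying covariates or effects.
* Gamma frailty only (no log-normal), one frailty shared across relapse
  ranks; no stratification.
* Smoothing parameters are fixed by configuration, not estimated; the LCV
  helper supports manual grids.
* Spline hazards refuse to extrapolate: prediction horizons are limited by
  the follow-up support of the fitting data.
* The landmark model summarizes history by relapse count alone.
* Fitting keeps the Laguerre likelihood rule along the whole optimization
  path; if the optimizer visits $\theta > 2$ with $\alpha$ far from 1 the
  integral there is slightly less accurate than the post-fit evaluation
  (which switches rules). In the intended regimes ($\hat\theta \lesssim
  1.5$) the difference is negligible.
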
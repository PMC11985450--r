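---
title: "Forecasting cancer incidence and prevalence with apcprev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting cancer incidence and prevalence with apcprev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcprev)
```

## The problem

Cancer registries tally *incident* cases well, but the population that
matters for survivorship care is the *prevalent* one: people alive today who
were diagnosed within the last $T$ years.  Prevalence is hard to measure
directly and is inherently retrospective — this year's survivor cohort
includes people diagnosed up to $T$ years ago, including years before the
registry existed.  `apcprev` estimates and forecasts prevalence as the
convolution of lagged incidence with survival after diagnosis, with both
pieces modelled so that they can be extrapolated forward (forecasting) and
backward (the "burn-in" back-cast) in calendar time.

## The incidence model

Incidence data form a Lexis diagram: case counts $Y_{pa}$ and person-years
$O_{pa}$ on an age $\times$ period grid with a common bin width $\Delta$, so
that birth cohorts $c = p - a$ run along the diagonals.  The model for the
expected log rate $\rho_{pa}$ is the log-linear age–period–cohort (APC)
model.  Because the three linear trends are jointly non-identifiable, the
package works exclusively through estimable quantities:

* the grand mean $\mu$;
* the longitudinal age trend $(\alpha_L + \pi_L)$ and the net drift
  $(\pi_L + \gamma_L)$ (the cross-sectional age trend is their difference);
* complete deviations $\tilde\alpha_a$, $\tilde\pi_p$, $\tilde\gamma_c$,
  each orthogonal to the constant and linear functions of its own index,
  and each further split as $\tilde\pi_p = \theta_\pi q^2_p(p) + \check\pi_p$
  into an orthogonal-quadratic curvature term and higher-order residuals.

No "equal split" of the linear trends is ever reported.  Orthogonalization
uses unweighted inner products on the (equally spaced) grid labels: the
deviation bases come from a QR decomposition against $\{1, x\}$, and $q^2$
is $x^2$ Gram–Schmidted against $\{1, x\}$ and scaled to unit Euclidean
norm.  $\theta$ is therefore basis-dependent; only the product
$\theta\,q^2(\cdot)$ is reported or used downstream.  The polynomial
coefficients of $q^2$ are retained so the curvature curve can be evaluated
beyond the grid.

`fit_apc()` fits this parametrization by Poisson regression with offset
$\log O$ (default) or by weighted least squares on log rates with weights
$Y$ (zero cells get $+0.5$ inside the log only).  Under
`family = "quasipoisson"` the covariance is scaled by Pearson
$\chi^2/\mathrm{df}$, floored at 1.

The fitted surface factors into estimable functions two ways:

$$R(a,p) = \mathrm{LongAge}(a \mid c_0)\,\mathrm{CRR}(c \mid c_0)\,
            e^{\tilde\pi_p}
         = \mathrm{CrossAge}(a \mid p_0)\,\mathrm{PRR}(p \mid p_0)\,
            e^{\tilde\gamma_c}.$$

We normalize the rate-ratio curves exactly at their references
($\mathrm{CRR}(c_0 \mid c_0) = \mathrm{PRR}(p_0 \mid p_0) = 1$) by
re-anchoring, with the reference terms absorbed into the age curves; the
product identity above is exact either way.  Default references are the
period nearest the period centre and the fully supported cohort nearest the
cohort centre, both user-overridable.  The two assemblies agreeing
cell-for-cell (at $10^{-8}$) is one of the package's standing checks.

## Trend extrapolation

Projections need the rate-ratio curves beyond the data.  `apcprev` fits the
log rate-ratio curves with a joinpoint-style piecewise-linear model
(`fit_piecewise_linear()`): an exhaustive search over interior knots placed
on observed index values, each candidate fit by weighted least squares on
the hinge basis $(x - \tau)_+$, with inverse-variance weights.  The knot
count is chosen by BIC on the weighted Gaussian likelihood, charging two
parameters per knot (location and slope change); ties prefer fewer knots.
The canonical permutation test of the surveillance JoinPoint program is
deliberately out of scope — BIC is deterministic, fast, and works well with
the conservative defaults (`max_knots = 3`, at least 3 observations per
segment).  Two numerical details matter:

* The residual variance entering BIC is floored at a tiny multiple of the
  response scale, so that *noise-free* signals (where every knot count fits
  exactly) tie and resolve to zero knots rather than chasing rounding error.
* Weights for the CRR/PRR fits are inverse *unanchored* delta-method
  variances of the log rate-ratio functional.  The anchored variance is
  exactly zero at the reference (the curve is pinned there), which would
  give one observation infinite weight; the unanchored variance is positive
  everywhere and shares the same shape information.

Beyond either data end the fit continues exactly linearly — the terminal
segment forward, the first segment backward (the same symmetric rule is
used for back-casting, since nothing in the model distinguishes the two
directions).  `fit_bspline_trend()` offers a B-spline alternative with
fixed knots at weighted quantiles and the same linear-tail contract, via
the boundary derivative.  Counterfactuals modify only the extrapolation:
`flatten_tail()` zeroes the tail slope ("horizontal" scenarios) and
`scale_slope()` multiplies it (e.g. $0.5\times$ / $1.5\times$ the observed
rate of change); fitted values inside the data range are never touched.
Reported extrapolation variances are conditional on the selected knots;
selection uncertainty is not propagated, which understates variance
slightly and is documented here rather than hidden.

## Incidence forecasting

`forecast_incidence()` extends the fitted surface over `h_fwd` future and
`h_back` past periods under two forms.  Under the **age–cohort (AC)** form,
a projected cell is the longitudinal age curve times a cohort term times a
period-curvature factor: cohorts observed in at least one cell keep their
*fitted* rate ratio; unobserved cohorts use the joinpoint extrapolation of
log CRR.  Under the **age–period (AP)** form, the cross-sectional age curve
is multiplied by the extrapolated PRR for all projected cells, with
partially observed cohorts contributing their fitted deviations and
unobserved cohorts a cohort-curvature factor.

The third-variable curvature factor continues $\theta q^2$ anchored
multiplicatively at 1 at the last observed period (or cohort):
`"linear"` compounds the boundary slope of $\theta q^2$ per projected step,
`"quadratic"` continues the full parabola relative to its boundary value,
and `"none"` omits the factor.  Anchoring at the boundary keeps the
projection continuous with the model's own boundary cells; it also makes a
"horizontal" extension of the factor identical to `"none"` (the frozen
boundary value is 1).  That identification is what reduces the nominal
$2 \times 2 \times 4$ cross of {form} $\times$ {rate-ratio extrapolation:
linear, horizontal} $\times$ {deviations: quadratic, linear, horizontal,
none} to exactly **12 distinct models**, which `enumerate_model_set()`
groups by whether trends are extrapolated for both period and cohort (4
models), period only (3), cohort only (3), or neither (2).  The four
*basic* models are the two forms with and without the linear curvature
trend.  `average_models()` combines any such set by the cell-wise mean,
with uncertainty either as the mean of variances or as the union span of
the members' confidence intervals.

Cell variances combine the APC delta-method variance (every non-joinpoint
term is a linear functional of the fitted coefficients, including the
curvature factors through $\theta$) with the joinpoint extrapolation
variance, treating the two stages as independent.  The forecast object
retains both functional matrices, which is what allows exact first-order
covariances between any two cells later in the pipeline.

## The survival model

Survival after diagnosis is tabulated from the case listing into
$M_{a,p,t}$ (at risk) and $D_{a,p,t}$ (all-cause deaths), $t = 0,\dots,T$
periods since diagnosis, where $t = 0$ means death in the diagnosis period
and follow-up is censored at $T$ (10 by default, mirroring common
registry practice).  The hazard model is additive on the log scale,

$$\ln \frac{E[D_{a,p,t}]}{M_{a,p,t}} = \nu + f_T(t) + f_A(a) + f_P(p),$$

fitted as a Poisson GLM with offset $\log M$ — the standard discrete-hazard
approximation, accurate for the small per-period hazards typical of cancer
survival (a binomial likelihood differs negligibly there).  Components are
piecewise-linear splines with joinpoint-selected knots (coordinate-wise
exhaustive BIC search, by default up to 2 knots in $t$ and 1 in $a$ and
$p$) or anchored B-splines with knots at quantiles (default 4 free
parameters per component, bounded by the number of distinct axis values).
Each component is zero at its axis minimum, so $\nu$ is the log hazard at
the grid origin.  Survival ages arrive in 5-year groups and enter at their
midpoints, `start + (width - 1)/2`; evaluating the fitted splines at exact
ages then resolves the resolution mismatch with single-year incidence
grids implicitly.  All components extrapolate linearly on the
linear-predictor scale in both directions — the period component is the
one that matters, carrying survival trends into past and future diagnosis
years — and `flatten_tail()` / `scale_slope()` apply to them for
counterfactuals.  Hazards are capped at $1 - 10^{-6}$ before forming
$1 - h$.

Cumulative survival uses the discrete product
$S(i) = \prod_{j=0}^{i} (1 - h_j)$, which is the exact object for
discrete-period tallies; the continuous-time approximation
$\exp(-\sum h_j)$ is available behind `survival_method = "exp"` for
sensitivity analysis but is not the primary contract, since the two differ
noticeably once hazards are not small.

## Prevalence as a convolution

With incidence rates $\lambda$ on the extended (back-cast + observed +
forecast) grid and the fitted survival model, the prevalence rate is

$$\xi_{pa} = \sum_{i=0}^{T} \lambda_{p-i,\,a-i}\; S(a-i,\, p-i,\, i),$$

each elapsed period ageing a cohort by exactly one age bin (hence the
enforced common $\Delta$).  People dying in their diagnosis period never
enter the prevalent cohort ($i = 0$ uses $1 - h_0$), and prevalence is
anchored at period end.  Terms whose diagnosis age falls below the youngest
modelled age contribute zero — such cohorts were not eligible for counted
diagnosis, mirroring registry analyses that start at a fixed age floor —
and do not make a cell incomplete.  Terms whose diagnosis period precedes
the extended grid are genuinely missing: with a back-cast horizon of at
least $T$ every reported cell is complete, and with back-casting disabled
the first $T$ periods are reported with `complete_mask = FALSE` rather than
dropped.

Uncertainty comes from a parametric bootstrap
(`bootstrap_covariance()`): replicate counts $Y^* \sim
\mathrm{Poisson}(\lambda O)$ cell-wise, replicate rates $Y^*/O$ convolved
against the *fixed* survival fit, and the sample covariance of the
flattened replicates taken as the $AP \times AP$ covariance.  Holding the
survival fit fixed follows the estimation procedure exactly; an analytic
complement, `prevalence_delta_var()`, propagates both the incidence-stage
functionals (exactly, including cross-cell covariance along each
convolution diagonal) and the hazard-coefficient covariance to first
order, and is what the validation suite uses to calibrate oracle
comparisons.

## Counts

`apply_population()` turns any rate surface into expected counts —
incident burden or prevalent survivorship — against census estimates or
projections, which enter as constants (no census uncertainty is
propagated).  Group totals use the population-weight vector through the
full covariance when available, otherwise independent-cell propagation.

## What the synthetic generators emulate

`truth_spec()` defines a registry-style world: by default 55 single-year
ages (30–84) by 28 periods (1992–2019), $10^6$ person-years per cell, log
incidence $-9$ at the centre with age slope $0.04$/yr and net drift
$0.01$/yr, optional quadratic curvatures, cohort-trend kinks and
higher-order wiggles; survival with baseline per-period hazard
$e^{-2.5} \approx 0.08$, declining in $t$, rising in age, improving
$2\%$/yr in period, reported in 5-year age groups.  These are the orders of
magnitude of a large cancer registry (the overall scale of a common solid
tumour in a multi-registry catchment), chosen once and used unchanged by
the validation suite.

`generate_lexis()` draws Poisson counts from the truth surface;
`generate_case_listing()` draws discrete survival times by sequential
per-period death probabilities at the age-group midpoint, censoring at the
study end; `microsim_prevalence()` walks individuals through the Lexis
plane — Poisson diagnoses on a period axis starting $T$ periods before the
window, multinomial death times at each individual's own fine age — and
head-counts survivors per cell.  The microsimulation never references the
convolution formula, which makes it a genuinely independent oracle.

What the generators do *not* emulate: reporting delay, missing or
time-varying subtype classification, population change within cells,
attained-age effects on survival (the hazard is indexed by age *at
diagnosis*, as in the fitted model), and model misspecification beyond the
planted kinks.  Passing tests therefore demonstrate correctness of the
estimators and their calibration under the model, not robustness to the
artefacts of real registry data.

## Validation design and problem sizes

The validation suite works at sizes chosen to make each check sharp but
quick: the full 55 × 28 grid for drift recovery (200 replicates; Wald
coverage required within 90–99%), 28-point series for joinpoint
localization (100 replicates, kink recovered within ±1 year at least 90%
of the time), roughly $10^5$ subjects for survival-trend recovery, and
three truth configurations (flat, drifting, kinked cohort trend) of
roughly $10^6$ expected diagnoses each for the prevalence oracle.  The
oracle comparison requires every cell within 3 standard errors, where the
standard error combines microsimulation noise ($\xi/O$, exact for Poisson
thinning) with the pipeline's own first-order estimation variance from
`prevalence_delta_var()`; with 300 correlated cells per configuration the
observed maximum $|z|$ sits near 3 even for a correct implementation, so
an honest variance calculation — not a padded tolerance — is what makes
the check pass.

## Design choices where the ground was open

* **Knot-selection rule**: BIC with 2 parameters per knot, not a
  permutation test — deterministic and cheap; documented above.
* **Back-casting** reuses the first joinpoint segment (symmetric to
  forward extrapolation) rather than refitting on reversed data.
* **Third-variable anchoring** at 1 at the boundary (continuity), with the
  consequence that horizontal deviation extensions equal "none" and the
  model taxonomy has exactly 12 distinct members.
* **Reference normalization** of CRR/PRR exactly at $c_0$/$p_0$, with the
  anchor terms absorbed into the age curves.
* **Discrete product** for survival accumulation, with $\exp(-\sum h)$ as
  a flagged alternative.
* **Bootstrap holds survival fixed**; hazard-coefficient uncertainty is
  available analytically through `prevalence_delta_var()` instead.
* **Stage independence** for variance combination (APC vs joinpoint;
  incidence vs survival): the stages are estimated from different data
  slices, and no joint model is attempted.

## Known limitations

Variances are conditional on selected knots; the age–incidence curve is
assumed to change amplitude, not shape, across cohorts and periods; the
12-model taxonomy is one defensible reading of a figure-only enumeration
and is configurable through `forecast_incidence()`'s options; and, as with
all trend extrapolation, the forecasts are snapshots under "trends
continue" — scenario analysis via `scale_slope()` and model averaging are
the intended ways to express that uncertainty.
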
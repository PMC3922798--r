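---
title: "Calibration coefficients for surrogate PM2.5 exposures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration coefficients for surrogate PM2.5 exposures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmcalib)
```

## The problem

Long-term epidemiologic studies of fine particles (PM2.5) rarely measure what
they care about. The exposure of interest — the portion of a person's PM2.5
exposure that originates outdoors — is replaced by a surrogate: the ambient
concentration at the nearest regulatory monitor, or a spatio-temporal model's
prediction outside the home. Both surrogates carry measurement error, and
classical-type error attenuates health-effect estimates toward the null.

A *calibration coefficient* quantifies this attenuation: it is the slope
$\gamma_1$ from regressing the "true" exposure $X$ on the surrogate $Z$.
A coefficient of 1 means no systematic distortion; a coefficient of 0.5 means
a linear health effect estimated with that surrogate would be roughly half
the true effect, all else equal. `pmcalib` estimates these coefficients from
multi-city personal-monitoring panel data (or from synthetic data with known
truth), tests whether they differ across cities, tries to explain any
between-city differences with city-level characteristics, and cross-validates
that explanation.

## True exposures

Personal PM2.5 of ambient origin cannot be measured directly. Where personal
and ambient sulfate are available, the package uses the sulfate tracer:
sulfate has negligible indoor sources and spatial homogeneity similar to
PM2.5, so the personal/ambient sulfate ratio approximates the infiltration
fraction, and

$$X^{\mathrm{amb}} = \frac{\mathrm{SO_4^{pers}}}{\mathrm{SO_4^{amb}}}\,
\mathrm{PM_{2.5}^{amb}}.$$

`ambient_origin_tracer()` implements this; `ambient_origin_timeweighted()`
implements the time-weighted variant used where personal sulfate is missing
(indoor ambient-origin concentration and ambient concentration weighted by
time spent indoors/outdoors, given a home infiltration efficiency). Total
personal PM2.5 serves as a second, imperfect truth definition: it includes
indoor- and personally-generated particles and is available for all
subjects.

Two tracer aggregation choices exist because days with valid sulfate are
scarce. By default the ratio of *monthly mean* sulfate concentrations
multiplies the monitor mean over the personal sampling days; this is robust
to day-level noise in low ambient sulfate. The day-level alternative
(average of daily tracer values) is available via
`build_analysis_table(tracer = "mean_of_daily")`.

## The analysis unit and eligibility

`build_analysis_table()` converts daily records into person-months: monthly
averages of personal exposure paired with two monthly surrogates. Subjects
younger than 18 are excluded, matching the adult focus of chronic-mortality
studies. The nearest monitor is assigned by haversine great-circle distance
(sphere radius 3958.8 miles) with a 30-mile cap — the conventional
monitor-matching rule — and exact ties break by monitor id so runs are
deterministic. The monitor surrogate uses all days in the month by default;
`monitor_mode = "matched_days"` restricts to the personal sampling days,
falling back day-by-day to the nearest monitor with data. A single sampled
day suffices to form a monthly mean by default (`min_days_per_month = 1`),
since real panel sessions can be as short as two days; raise it to demand
denser months.

Season is deterministic from the calendar month: October–March is winter,
April–September summer. Winter is coded 1 in the models (the choice does not
affect $\gamma_1$; it decides which season the main effect refers to when a
season interaction is present).

## The calibration models

The pooled model (fit with `fit_calibration(model = "model1")`) is

$$X_{ijk} = (\gamma_0 + g_{1i} + g_{2ij}) + (\gamma_1 + g_{3i})Z_{ijk}
+ \gamma_2\,\mathrm{Winter}_{ijk} + \varepsilon_{ijk},$$

for subject $j$ in city $i$ and month $k$, with independent
$g_{1i}\sim N(0,\sigma^2_{\mathrm{city}})$,
$g_{2ij}\sim N(0,\sigma^2_{\mathrm{subject}})$,
$g_{3i}\sim N(0,\sigma^2_{\mathrm{CF\text{-}city}})$ and
$\varepsilon_{ijk}\sim N(0,\sigma^2_W)$. Estimation is REML via `lme4`
(ML by flag). Three structural choices deserve note:

* **Compound symmetry within subject** arises from the subject random
  intercept, which induces exchangeable positive correlation among a
  subject's months. A separate exchangeable residual block would be
  redundant with it (the marginal covariance family is identical) and is
  deliberately not implemented, avoiding a non-identifiable decomposition.
* **The city intercept and city slope are independent**, i.e. no
  intercept–slope covariance. A consequence worth knowing: with an
  uncorrelated random slope the marginal covariance depends on the origin of
  $Z$, so Model 1 is not invariant to centering the surrogate (Model 2 is).
  Estimates are still equivariant under rescaling of $X$.
* **Wald inference with normal quantiles** for CIs and the test of
  $\gamma_1=1$, $(\hat\gamma_1-1)^2/\widehat{var}(\hat\gamma_1)\sim\chi^2_1$.
  No Satterthwaite/Kenward-Roger correction is applied; with roughly ten
  cities informing the slope variance this makes intervals mildly
  anti-conservative (simulated coverage around 0.92–0.93 at the default
  design rather than 0.95), which the calibration tests account for.

`model2` drops the city random slope; `model3` adds city-covariate main
effects and surrogate interactions; `model4` is a single-city fit with
subject intercepts only. Variance components estimated below
$10^{-8}\,\mathrm{var}(X)$ are flagged as boundary cases. Fits that fail
`lme4`'s default optimizer are retried with bobyqa; persistent
non-convergence is reported in the `converged` flag rather than raised.
City covariates in `model3` are z-scored across cities by default
(comparable interaction magnitudes for selection); per-raw-unit coefficients
— e.g. the effect of one additional vehicle per housing unit — require
`standardize_covariates = FALSE`.

## Between-city heterogeneity

Whether one national calibration coefficient suffices is the hypothesis
$H_0:\sigma^2_{\mathrm{CF\text{-}city}}=0$, tested by comparing Models 1 and
2 with a REML likelihood-ratio test (valid: both models share fixed
effects). Because the null value lies on the boundary of the parameter
space, the statistic is referred to a 50:50 mixture of $\chi^2_0$ and
$\chi^2_1$: `mixture_lrt_p()` returns exactly 0.5 when the slope variance is
estimated at zero and $0.5\,(1-\chi^2_1(\mathrm{LRT}))$ otherwise. Ignoring
the boundary (plain $\chi^2_1$) is conservative; the test suite checks this
directionally. Small negative LRT values can arise from finite optimizer
tolerance; values within $10^{-6}$ are clipped to zero (after refitting the
slope model from alternative optimizers), anything more negative is treated
as a fitting fault and raised.

When heterogeneity is found, `stepwise_city_covariates()` runs forward
selection over candidate city variables: at each step the candidate whose
surrogate interaction has the smallest Wald p-value below $\alpha$ enters,
and selection stops when none qualifies. Forward (rather than backward)
selection is the only workable direction with fewer than ten cities, where
a full candidate set is immediately rank-deficient; near-collinear
candidates are skipped with a warning for the same reason. After selection
the *residual* heterogeneity is re-tested by the same boundary-mixture LRT
on the final model's random slope.

## Cross-validating the explanation

With few cities, a covariate can "explain" heterogeneity by accident.
`loocv_city_coefficients()` guards against this: each city is left out in
turn, selection and fitting are repeated on the remaining cities (the
held-out city's rows never enter, enforced by an assertion on the training
index set), and the omitted city's coefficient is predicted as
$\hat\gamma_{1i}^- = \hat\gamma_{1(-i)} + \sum_c \hat\gamma_{4c(-i)}
\mathrm{CityVariable}_{ci}$, with covariates transformed by the training
fold's scaling. Predictions are compared with the observed city-specific
coefficients (independent `model4` fits) via Pearson correlation (Spearman
by flag), mean relative bias and mean absolute relative bias. Observed
coefficients of exactly zero are excluded from the ratio metrics. Forest
plots of the city-specific estimates (`plot_city_forest()`) size each point
by the inverse variance of that city's coefficient.

## The synthetic-data generator

No personal-monitoring panel of this kind is publicly deposited, so the
generator is a first-class module: every downstream stage is exercised
against data with known truth. Its defaults describe the study conditions
the package targets: nine cities, 30 subjects per city, six consecutive
monitored months per subject with staggered start months (so both seasons
occur), seven sampling days per month; a city-month ambient field of
15.86 ± 5.58 µg/m³ and per-subject sulfate ratios of 0.64 ± 0.25 truncated
to [0, 1.5] (infiltration is a property of home and behavior, hence stable
within subject); non-ambient personal PM2.5 of mean 14.8 µg/m³ (the gap
between typical total-personal and ambient-origin means); adult ages uniform
on 40–90, with minors only via an explicit flag to exercise the eligibility
filter; a calibration slope of 0.54 with city-slope SD 0.15 (matching the
spread of city-specific coefficients such studies report), city-intercept SD
1, subject SD 2, residual SD 3, and a winter effect of −2 µg/m³ (ambient-
origin exposure runs lower in winter when infiltration drops). One monitor
sits two miles from each city centroid; residences scatter within ten
miles, so the 30-mile rule passes by construction unless
`distant_monitor_city` plants a far monitor.

Two modes serve different purposes:

* **`regression_truth`** draws the surrogate first (the all-days monthly
  monitor mean) and then generates $X$ *exactly* from the calibration model
  above. Daily personal values are constant within the month and the sulfate
  columns are constructed to reproduce $X$ through the tracer, so fitted
  coefficients are directly comparable to the configured truth. This is the
  mode behind the parameter-recovery and test-calibration checks.
* **`mechanistic`** simulates the physics: personal ambient-origin exposure
  is the subject's infiltration ratio times the day's ambient level, total
  exposure adds a non-ambient source, monitors observe the daily ambient
  level with instrument error, and model predictions observe the city-month
  level with error. The attenuation of the fitted slope is then emergent:
  with a constant ratio $r$ and error-free monitors it converges to $r$
  exactly.

Day-to-day ambient variation (`ambient_daily_sd`, default 0) is shared
between the monitor and — in mechanistic mode — personal exposure. Turning
it on reproduces the temporal-mismatch phenomenon: monitor means computed
over *all* days of the month are misaligned with the days a subject was
actually monitored, leaving point estimates similar but confidence intervals
wider than with matched-days averaging. The default of zero keeps the
regression-truth surface exact.

What the generator does *not* emulate: the covariate structure of real
spatio-temporal prediction models (predictions here are ambient plus
independent error), environmental tobacco smoke, multiple monitors per
city, instrument error in personal samplers (folded into $\sigma_W$
together with within-subject day-to-day variation, which the generator does
not separate), and real spatial correlation between cities. Passing tests
therefore demonstrate correctness of the estimators under the stated model,
not robustness to every feature of field data.

A note on truncation: monthly true exposures are floored at zero to respect
the physical range. Under the default parameters a negative draw has
probability well under 0.1%, so the induced bias is negligible; configuring
a small `gamma0` with a large `sigma_w` makes the floor active and the
recovery guarantees void.

## Numerical choices

* Variance components: `lme4`'s profiled REML with boundary detection at
  $10^{-8}\,\mathrm{var}(X)$; singular fits are legitimate boundary
  estimates, not errors.
* Negative LRT clip tolerance $10^{-6}$, after an optimizer-restart rescue.
* Ties in monitor distance break lexicographically; city fits are returned
  in city-id order.
* Truncated-normal draws use the inverse-CDF transform, so a fixed seed
  yields bit-identical datasets across platforms with the same RNG.
* Degenerate inputs are flagged, not guessed at: one observation per
  subject marks the subject/residual variance split non-identifiable; a
  constant surrogate within a city marks that city's slope non-identifiable;
  a single-season dataset is a rank-deficiency error naming the season
  column.

## Problem sizes

The simulation-based checks in the test suite use the package's reference
design of 10 cities × 30 subjects × 6 months: 100 replicates for parameter
recovery (mean $\hat\gamma_1$ within 0.02 of 0.54; CI coverage within
[0.90, 0.99]) and 500 null replicates for the size of the Wald test of
$\gamma_1 = 1$ and of the mixture LRT (both within [0.03, 0.08] at
$\alpha = 0.05$). These sizes give Monte-Carlo standard errors of about
0.005 on a coverage proportion and 0.01 on a rejection rate, small enough
to distinguish nominal behavior from miscalibration while keeping the full
suite to a few minutes.

## Limitations

The package estimates calibration coefficients; it does not correct
health-effect estimates with them, and the coefficients it produces should
not be plugged directly into a regression-calibration adjustment of
epidemiologic results: with heterogeneous, time-varying exposure error and
confounders measured at different scales, naive adjustment can itself bias
estimates. Small numbers of cities limit both the power of the
heterogeneity test and the stability of covariate selection — precisely the
situation the LOOCV diagnostics are there to expose.
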
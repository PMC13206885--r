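---
title: "Time-concentration-mortality analysis of insect bioassays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-concentration-mortality analysis of insect bioassays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmfit)
```

## The model and its assumptions

`tcmfit` analyses replicated cohort bioassays in which insects are exposed
once to one of several pathogen concentrations and observed daily. The core
model is conditional: among insects alive at the start of day $j$ at
$x = \log_{10}$ dose, the probability of dying during day $j$ is

$$q_j(x) = 1 - \exp(-\exp(\gamma_j + \beta x)),$$

a complementary log-log binomial with a single dose slope $\beta$ shared
across days and a free intercept $\gamma_j$ per day. The cloglog link makes
the per-day quantities genuine hazards: survival probabilities multiply, so
hazards add on the $\exp$ scale and cumulative mortality by day $j$ keeps
the same functional form with intercept

$$\tau_j = \log \sum_{k \le j} \exp(\gamma_k),$$

computed in `accumulate_tau()` by overflow-safe log-sum-exp. This identity
is what lets one parameter table serve both the conditional view (which day
kills) and the cumulative view (endpoints).

Assumptions worth stating plainly:

* a shared $\beta$ — dose changes the level of the daily hazard but not its
  time profile;
* independence of insects within and across cohorts (no cage effects, no
  between-replicate overdispersion);
* natural (control) mortality acts as an independent competing risk, so
  survival probabilities of the two causes multiply — the regime in which
  Abbott's correction is approximately the right de-confounder;
* discrete observation days; nothing is inferred about within-day timing
  beyond interpolation of the predictor (below).

## Data reduction and control correction

Raw input is a long table of cumulative counts, one row per
(dose, replicate, day). `to_interval_data()` differences it into the
likelihood's sufficient data: per (dose, day), the number at risk at the
start of the day and the deaths during it. Replicates are pooled (summed)
by default because the model has a single parameter set per assay; whether
the original analyses pooled or fitted replicate-level counts is not
documented in the sources this design follows, so pooling is the default
and `pool_replicates = FALSE` is available.

`corrected_interval_counts()` applies Abbott's correction
$(T - C)/(1 - C)$ day by day to cumulative mortality against the same-day
control, clamps negative values at zero, enforces monotonicity of the
corrected series by a running maximum, and re-expands to fractional
effective counts on the original cohort size. The binomial likelihood
accepts these fractional counts as quasi-counts: this preserves a single
likelihood code path at the cost of treating corrected data as if it
carried binomial information. One visible consequence, measured on
synthetic assays: with correction switched on, the sampling spread of
$\hat\beta$ at 25 x 3 scale is some 30-40% wider than the
information-matrix SE suggests, whereas on raw model-true data the two
agree within ~10%. Corrected-fit SEs should therefore be read as
approximate.

## Fitting and numerical choices

`fit_tcm()` maximises the conditional binomial log-likelihood by BFGS with
an analytic gradient (falling back to a `nlminb` polish if BFGS reports
non-convergence), starting from $\beta = 0.5$ and
$\gamma_j = \mathrm{cloglog}(\bar q_j) - \beta \bar x$ clamped to
$[-12, 2]$, where $\bar q_j$ is the pooled observed conditional mortality
of day $j$. Days with no deaths at any dose carry no information about
their $\gamma_j$; such days are flagged degenerate, fixed at a floor of
$-18.8$ (a daily hazard of about $7 \times 10^{-9}$ — effectively zero but
smooth), and excluded from the information matrix, so their SEs and t
statistics are reported as not applicable rather than as a meaningless
boundary ratio. The delta method supplies $\mathrm{Var}(\tau_j)$ and
$\mathrm{Cov}(\tau_j, \beta)$ with
$\partial\tau_j/\partial\gamma_k = \exp(\gamma_k - \tau_j)$. On the
cumulative-parameter side of a reported table the row for $\beta$ itself
carries $\mathrm{Var}(\beta)$, since a covariance of $\beta$ with itself in
the $\tau$ column has no separate meaning.

Identifiability guards: at least two distinct positive doses are required
(one dose cannot separate $\beta$ from the intercepts); complete mortality
on day 1 everywhere leaves no time structure and is refused; control
(dose 0) rows never enter the likelihood directly — they act only through
the correction.

## Goodness of fit

`hosmer_lemeshow()` groups the (dose, day) cells — not individual insects —
by sorted predicted probability into ten near-equal groups (ties broken by
dose then day, so results do not depend on input order), and compares
observed and expected deaths with
$C = \sum_g (O_g - E_g)^2 / (E_g(1 - E_g/n_g))$, $df = g - 2$. With the
reference design of 6 doses x 7 days = 42 cells, ten groups give $df = 8$.
The $df = g - 2$ convention is a heuristic borrowed from grouped logistic
goodness of fit; on model-true synthetic assays at reference scale the test
is mildly conservative (rejection rate near 0.02-0.05 at nominal 0.05),
which the calibration test in the suite checks with a Monte-Carlo
tolerance.

## Lethal endpoints

`lc_p()` inverts the cumulative model in closed form. `lt_p()` treats the
cumulative predictor $\eta(t) = \tau(t) + \beta x$ as piecewise linear in
$t$ between observation days and solves for the crossing of
$\ln(-\ln(1-p))$. Design choices here:

* **Interpolation scale.** Linear in $t$ reproduces the reference
  lethal-time table to ~1.5% (e.g. 4.98 days at $10^6$ conidia/mL for
  larvae, to the printed precision); linear in $\log_{10} t$ is available
  via `interpolation = "log10"` for users who prefer hazard interpolation
  on the log clock. The exact rule used by the legacy DPS software is
  unpublished; residual deviations at the percent level are attributable to
  this plus the 3-decimal rounding of published parameters.
* **$t = 0$ anchor.** If the level is crossed within day 1 the root is
  taken between a floor predictor at $t = 0$ (default $-18.8$) and
  $\tau_1$, so early crossings interpolate instead of truncating.
* **No extrapolation.** A level not reached by the last observation day is
  returned with `estimable = FALSE` and rendered as an em dash, matching
  bioassay reporting convention; extrapolating the model beyond the
  observation horizon would manufacture precision the data do not contain.
* Confidence intervals on endpoints are not produced, but
  $\mathrm{Var}(\tau_j)$ and $\mathrm{Cov}(\tau_j,\beta)$ are stored so a
  delta-method interval can be added without refitting.

## The synthetic assay generator

`simulate_assay()` is the generative twin of the fitted model: survivors
transition daily with conditional probability $q_j$(dose), composed
multiplicatively with an independent natural-mortality hazard (default
0.005/day, a realistic few-percent weekly background for healthy
laboratory cohorts) that also drives the dose-0 control. The reference
scenario (`stage_scenario()`) uses the published parameter sets and the
reference design: doses $10^3$-$10^8$ conidia/mL by decades, 25 insects x 3
replicates, 7 days. One top-level seed deterministically derives one RNG
stream per (dose, replicate) cohort, so tables are bit-reproducible.

What passing synthetic tests does and does not show: the generator has no
between-replicate overdispersion, no cage or handling effects, no
time-varying background hazard, and its hazards follow the fitted family
exactly, so recovery and calibration results validate the estimation
machinery, not the biological adequacy of the cloglog form for any given
real assay — that is what the heterogeneity test is for on real data.

## Problem sizes in the test suite

The validation suite fits 200 simulated assays at reference scale for slope
recovery (mean $\hat\beta$ within $\pm 0.1$ of the generating 0.748, and
within $\pm 0.05$ for a single 2000-insect-per-dose assay), 500 for
heterogeneity-test calibration, and checks the optimizer against a dense
brute-force grid on a 2-dose x 2-day toy assay; these sizes give
Monte-Carlo standard errors comfortably below the tolerances tested while
keeping the whole suite under a minute.

## Known limitations

* Corrected (fractional) counts are quasi-likelihood, not exact binomial;
  SEs under heavy control mortality are approximate.
* No random effects over replicates; overdispersed assays will look like
  lack of fit rather than being absorbed.
* No continuous-time survival model; lethal times are interpolations of a
  daily model, not event-time estimates.
* The published parameter sets bundled for the worked examples are
  transcribed at 3-decimal precision, which bounds how exactly endpoints
  derived from them can reproduce the corresponding published values
  (about 1-2%).
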
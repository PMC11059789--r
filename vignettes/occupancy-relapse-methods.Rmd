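---
title: "Receptor occupancy and relapse after antipsychotic discontinuation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor occupancy and relapse after antipsychotic discontinuation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occrelapse)
```

## The scientific problem

When a maintenance antipsychotic is discontinued in a placebo-controlled
trial, the drug does not vanish at randomization: plasma levels — and with
them striatal dopamine D2 receptor occupancy — decay over days (oral
formulations) to months (long-acting injectables, LAI). Whether relapse
risk tracks the *rate* at which occupancy falls, its *absolute level*, or
simply time off treatment has direct consequences for tapering practice.
This package implements the full analysis chain for that question:
deterministic occupancy trajectories per formulation and arm, a synthetic
individual-patient trial generator driven by those trajectories, and the
four survival analyses (treatment effect by formulation, time-varying
hazard ratio, rate-of-change effect, absolute-occupancy effect) with
random-effects meta-analytic pooling.

Real individual patient data for such programs are access-controlled, so
the package treats the *synthetic generator as the data source*: the
analyses are validated by parameter recovery against known generative
truths rather than against any proprietary dataset.

## The occupancy model

Occupancy follows a saturating Emax relation in the plasma dose-equivalent
$d$ (mg/day):

$$\mathrm{occ}(d) = \mathrm{occ}_{max} \frac{d}{d + \mathrm{ED}_{50}},
\qquad \mathrm{ED}_{50} = 2.38 \text{ mg/day}, \quad
\mathrm{occ}_{max} = 100\%.$$

A trough occupancy of 80% at randomization — the level at which efficacy is
considered maximized without severe extrapyramidal side effects after a
stabilization period — fixes the trough plasma equivalent at
$2.38 \times 80/20 = 9.52$ mg/day. Sensitivity profiles use 75% and 85%.

For injectables at steady state, the post-injection peak must decay
first-order back to the trough over the remainder of the dosing interval,
so

$$\mathrm{peak} = \mathrm{trough} \times
2^{(\mathrm{interval} - t_{peak})/t_{1/2}},$$

giving peak occupancies that round to 86% (1-monthly: $t_{peak}$ 5 d,
interval 30 d, $t_{1/2}$ 37 d) and 85% (3-monthly: 28 d, 90 d, 111.5 d).
Within a cycle, *plasma* (not occupancy) rises linearly from trough to peak
and then decays exponentially; occupancy is the pointwise Emax transform.
Because the Emax curve is concave, occupancy always decays more slowly than
plasma — the pharmacological reason why even slow plasma washout translates
into long periods of residual receptor blockade.

```{r trajectories, fig.width = 7, fig.height = 4.5}
cfg <- default_analysis_config(seed = 1)
traj <- run_trajectories(cfg)
occrelapse:::plot_trajectory_set(traj$trajectories)
```

Design choices where the underlying description is open:

* **Daily grid, day 0 = randomization.** The analyses use daily estimated
  occupancy, so finer grids add nothing. Randomization is taken to coincide
  with a scheduled dosing time: active arms receive an injection at day 0
  with plasma at trough, placebo arms decay from that same trough.
* **Oral kinetics.** Oral active treatment is modelled as a constant daily
  plasma-equivalent (daily averaging of a once-daily dosing cycle). The
  oral placebo arm decays with a configurable washout half-life defaulting
  to 1 day — occupancy reaches approximately zero within days, which is
  precisely why oral trials are excluded from the occupancy and rate
  analyses.
* **Rate convention.** The daily rate of change is the forward first
  difference of occupancy assigned to the start day of each one-day
  interval; the final grid point carries the last defined difference. At a
  daily grid this differs from the analytic derivative by under 1%.
* **Steady state from day 0.** Active-arm accumulation is assumed complete
  at randomization (participants were stabilized before entry), so the
  sawtooth is periodic from the first day.

## The trial generator

Each trial is parallel-group with fixed arm sizes. The generative relapse
hazard on day interval $(d, d+1]$ is piecewise constant:

$$h(d) = h_0 \exp\!\big(\beta_g I_{active} + \beta_{occ}\,\mathrm{occ}(d)/10
+ \beta_{rate}\,\mathrm{rate}(d) + \beta_{t\times g} I_{active}\, d\big),$$

mirroring exactly the covariates the analyses estimate. Event times are
drawn by inverse transform on the accumulated daily hazard; dropout is an
independent exponential, rounded up to the end of its day (ties within a
day resolve to relapse); administrative censoring applies at the trial
horizon.

Defaults, chosen once as realistic for this class of trial:

* **Arm sizes and horizons** follow the five-trial program emulated
  (159/144, 164/170, 205/203, 105/102, 65/71; 487 days for 16-month
  follow-up, 426 for 14, 365 for 12, at 30.4375 days/month).
* **Baseline hazard** $h_0 = 0.002$/day at zero occupancy, giving on the
  order of 50% placebo relapse over a year once occupancy has washed out —
  the upper range of what placebo arms of discontinuation trials show.
* **Dropout** $5\times10^{-4}$/day, yielding roughly 15–20% non-relapse
  dropout; the original trials' censoring mechanisms are not described, so
  independent exponential censoring is a modelling convenience.
* **Generative effects** default to $\beta_{occ} = -0.34$ per 10
  percentage points (a plausible protective scale used for recovery
  experiments) and zero for the others.

What the generator deliberately does *not* emulate: between-patient
pharmacokinetic variability (identical kinetics are assumed across
participants), pre-randomization stabilization dynamics, adherence
behaviour, and any non-proportional or frailty structure. Passing recovery
tests therefore demonstrates that the analysis chain is consistent for data
generated under its own covariate model — not that real trial data meet
those assumptions.

## The survival analyses

**Counting-process construction.** Records expand to half-open daily
intervals $(d, d+1]$ carrying the day-$d$ covariate value (left-aligned),
then consecutive intervals with identical covariates are merged. The
compression is lossless: fits on compressed and strictly daily tables agree
to $10^{-8}$ (a tested invariant), and exposure time is conserved exactly.

**Cox models** use the Efron approximation for the frequent same-day ties
of a daily grid, Newton iteration capped at 50 steps, and strict
diagnostics: zero events, non-convergence, collinearity and apparent
infinite coefficients (monotone partial likelihood) raise errors rather
than returning silent estimates. Occupancy enters per 10 percentage points
(configurable) so coefficients are readable log hazard ratios; the rate and
occupancy terms are fitted in *separate* models, each adjusted for
randomization group as a constant covariate. In occasional simulated
replicates the group and occupancy covariates sit on a nearly flat
likelihood ridge (they are collinear within every risk set and separate
only through the time-variation of the occupancy gap); such fits are
flagged and the pipeline skips that trial explicitly rather than pooling a
degenerate estimate.

**Case-base model.** The smooth-in-time hazard is estimated by contrasting
all event person-moments with base person-moments sampled uniformly on
observed person-time (100 per case by default, sampled with replacement;
cases are not removed from the base). A logistic model of case status on
group, time and group-by-time is fitted by IRLS; under this sampling the
log odds of being a case equal the log hazard plus $\log(B/b)$, so slope
coefficients are log-hazard parameters directly and the intercept minus
the offset recovers the log baseline hazard. Time enters linearly on the
log-hazard scale — a single interaction coefficient, not splines — so the
time-varying hazard ratio is $\exp(\beta_g + \beta_{t\times g} t)$ with a
delta-method interval.

**Meta-analysis.** Per-trial coefficients are pooled within formulation
(and across all LAI trials) by DerSimonian–Laird random effects, the
long-standing default of the meta-analytic ecosystem; REML is available
behind a flag for sensitivity. The formulation moderator test is a plain
Wald chi-square from a fixed-effect inverse-variance meta-regression on
formulation indicators, with pairwise contrasts as z-tests; no small-sample
adjustment is applied, matching a plain Wald-type test. Statistical
significance is two-sided at 0.05 throughout, with no multiplicity
correction.

**Sensitivity analysis** re-runs every analysis with trajectories rebuilt
at each trough occupancy in the grid (75/80/85 by default). When data are
supplied (or simulated once), the same event times are re-analysed at every
trough: the trough assumption changes only the analysis covariates.

## Numerical and testing choices

* Cox convergence: log-likelihood tolerance $10^{-11}$, 50 iterations with
  step-halving; logistic fits: IRLS to $10^{-12}$, 100 iterations.
* Tiny-instance Cox fits are verified against a dense grid search
  (step $10^{-3}$) of an independently coded Efron partial likelihood;
  DerSimonian–Laird pooling against hand-computed formulas; the moderator
  test against normal-equations weighted least squares; the case-base group
  coefficient against the Cox log hazard ratio (within 5% on large
  constant-hazard simulations).
* Calibration experiments in the test suite use replicated simulation at
  fixed seed streams: 200 replicates of the full five-trial program for
  occupancy-effect recovery, 150 for the null-rate and time-interaction
  checks, 250–400 smaller replicates for type-I-error calibration, and
  $n = 50\,000$ single-arm simulations for Kaplan–Meier versus analytic
  survival agreement (sup-norm $\le 0.01$). Coverage assertions use
  binomial-noise bands around the nominal 95%, slightly widened at the low
  end because DerSimonian–Laird normal intervals are known to undercover
  with few trials ($k = 3$–$5$).
* Determinism: every stochastic entry point takes a seed; trial-level and
  case-base seeds are derived deterministically from the master seed, and
  an identical master seed reproduces byte-identical patient CSVs and
  reports (modulo a timestamp field).

## Known limitations

* The occupancy model is a single-compartment caricature: no absorption
  rate constants, no flip-flop kinetics, no inter-individual variability,
  and maximal occupancy fixed at 100% (exposed as a parameter).
* The unit of occupancy coefficients is a reporting choice (per 10
  percentage points by default) and must be kept in mind when comparing
  against estimates whose scale is unstated.
* The case-base model assumes log-linear time; a hazard ratio that changes
  non-monotonically would be summarized, not captured.
* Oral-formulation occupancy analyses are intentionally unsupported:
  occupancy collapses within days of oral discontinuation, leaving no
  usable time-variation.
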
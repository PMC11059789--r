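# occrelapse

Tools for studying how striatal dopamine D2 receptor occupancy relates to
psychosis relapse after antipsychotic discontinuation. The package is aimed
at researchers analysing (or planning) placebo-controlled discontinuation
trials of paliperidone-type antipsychotics, where individual patient data
are typically access-controlled: it provides the occupancy model, a
synthetic trial generator that stands in for such data, and the survival
analyses that relate occupancy trajectories to relapse risk.

## What it computes

**Occupancy trajectories.** Receptor occupancy follows the saturating Emax
relation

    occupancy(d) = occ_max * d / (d + ED50),

with ED50 = 2.38 mg/day (plasma dose-equivalent) and occ_max = 100%. A
trough occupancy of 80% at randomization (after stabilization) fixes the
trough plasma level at 9.52 mg/day-equivalents. For long-acting injectables
(LAI), plasma rises linearly from trough to the steady-state peak

    peak = trough * 2^((interval - t_peak) / half_life)

over the time-to-peak, then decays first-order back to the trough at the
next injection (1-monthly: t_peak 5 d, interval 30 d, half-life 37 d;
3-monthly: 28 d, 90 d, 111.5 d). Placebo arms decay first-order from the
trough. Oral active treatment is a constant daily level; oral occupancy
washes out within days of discontinuation.

**Trial simulation.** Five parallel-group discontinuation trials (arm sizes
159/144, 164/170, 205/203, 105/102, 65/71 — 1388 participants) are
simulated with a daily piecewise-constant relapse hazard whose log-linear
predictor can include randomization group, occupancy (per 10 percentage
points), its daily rate of change, and a group-by-time interaction.

**Survival analyses.** (i) per-trial Cox proportional-hazards models of the
treatment effect with a Wald-type formulation moderator test; (ii) a
case-base sampled smooth-in-time hazard model giving a time-varying hazard
ratio and a group-by-time interaction, pooled across trials; (iii) Cox
models with the daily rate of occupancy change as a time-varying covariate
(LAI trials only); (iv) Cox models with absolute daily occupancy (LAI
trials only); all pooled by DerSimonian-Laird random-effects meta-analysis,
plus sensitivity re-analysis at 75%/85% trough occupancy.

## Worked example

```r
library(occrelapse)

fp <- default_formulations()
round(occupancy_from_dose(steady_state_peak(fp$lai_1m), fp$lai_1m))
#> [1] 86    # peak occupancy, 1-monthly LAI: active arms span 80-86%
round(occupancy_from_dose(steady_state_peak(fp$lai_3m), fp$lai_3m))
#> [1] 85    # 3-monthly LAI: active arms span 80-85%

cfg <- default_analysis_config(seed = 1)   # occupancy effect -0.34 / 10 pts
report <- run_full_analysis(cfg)           # simulates 1388 subjects, analyses
report
#> Relapse analysis report (1388 subjects, 303 events, simulated)
#> Per-trial treatment effect (log HR):
#>   PSY-3012  (lai_3m): -1.457 (SE 0.426), HR 0.233
#>   SCA-3004  (lai_1m): -3.136 (SE 0.514), HR 0.043
#>   PSY-3001  (lai_1m): -2.095 (SE 0.298), HR 0.123
#>   SCH-301   (oral): -2.539 (SE 0.432), HR 0.079
#>   SCH-3041  (oral): -3.155 (SE 0.728), HR 0.043
#> Formulation moderator test: Q = 5.093 (df 2), p = 0.0783
#>   Pooled group x time interaction: -0.0013 (SE 0.0015), 95% CI [-0.0041, 0.0016], p = 0.374
#>   Pooled occupancy-rate coefficient (LAI combined): 0.1715 (SE 0.4448), 95% CI [-0.7003, 1.0432], p = 0.7
#>   Pooled occupancy coefficient per 10 pts (LAI combined): -0.0626 (SE 0.1195), 95% CI [-0.2967, 0.1716], p = 0.601
```

Because the generative hazard here is driven purely by occupancy (group
effect zero), every active arm is strongly protected (log HRs around -1.5
to -3), the moderator test finds no formulation difference, and the pooled
occupancy coefficient is negative (protective) — a single simulated program
is noisy, which is why the test suite judges recovery across hundreds of
replicates. `run_sensitivity(cfg)` repeats everything at 75/80/85% trough
occupancy; `write_report_json()` serializes any report.

A thin command-line wrapper with `simulate` / `trajectories` / `analyze` /
`sensitivity` verbs is installed at
`system.file("cli", "relapse-pipeline", package = "occrelapse")`, and a
bundled configuration at
`system.file("extdata", "default_config.yaml", package = "occrelapse")`.

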
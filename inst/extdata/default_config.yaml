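# Default configuration: formulation PK/PD constants, the five-trial
# discontinuation program, and the generative hazard used for simulation.
formulations:
  oral:
    ed50_mg_per_day: 2.38
    half_life_days: 1        # post-discontinuation washout (placebo arm)
    trough_occupancy_pct: 80
    max_occupancy_pct: 100
  lai_1m:
    ed50_mg_per_day: 2.38
    half_life_days: 37
    time_to_peak_days: 5
    dosing_interval_days: 30
    trough_occupancy_pct: 80
    max_occupancy_pct: 100
  lai_3m:
    ed50_mg_per_day: 2.38
    half_life_days: 111.5
    time_to_peak_days: 28
    dosing_interval_days: 90
    trough_occupancy_pct: 80
    max_occupancy_pct: 100
trials:
  - {trial_id: PSY-3012, formulation: lai_3m, n_active: 159, n_placebo: 144, max_followup_days: 487, dropout_hazard_per_day: 5.0e-4}
  - {trial_id: SCA-3004, formulation: lai_1m, n_active: 164, n_placebo: 170, max_followup_days: 487, dropout_hazard_per_day: 5.0e-4}
  - {trial_id: PSY-3001, formulation: lai_1m, n_active: 205, n_placebo: 203, max_followup_days: 487, dropout_hazard_per_day: 5.0e-4}
  - {trial_id: SCH-301,  formulation: oral,   n_active: 105, n_placebo: 102, max_followup_days: 365, dropout_hazard_per_day: 5.0e-4}
  - {trial_id: SCH-3041, formulation: oral,   n_active: 65,  n_placebo: 71,  max_followup_days: 426, dropout_hazard_per_day: 5.0e-4}
hazard:
  baseline_hazard_per_day: 0.002
  beta_group: 0.0
  beta_occ_per_10pct: -0.34
  beta_rate: 0.0
  beta_time_interaction_per_day: 0.0
seed: 20260101
trough_occupancy_grid: [75, 80, 85]
base_ratio: 100
occ_scale: 10
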
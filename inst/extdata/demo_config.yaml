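# Demonstration configuration for the full pipeline (small problem sizes).
seed: 1
scene:
  enabled: true
  height: 96
  width: 96
  n_nests: 2
  nest_axes: [10, 18]
  proliferation_fraction: 0.25
  noise_sd: 1
  n_fields: 6
cohort:
  source: simulate
  n_patients: 240
  log_hr: 0.6931472        # ln 2
  baseline_hazard: 0.004
  censor_rate: 0.002
grading:
  min_group_frac: 0.10
  biomarkers: [ki67_sum, ki67_ck_ratio]
survival:
  covariates: [t_stage, n_stage, histo_grade, er_positive, her2_amplified]
roc:
  horizon: 60
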
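model:
  cycle_length_months: 1.5
  survival_step_months: 1.0
  n_cycles: 80
  discount_rate:
    base: 0.05
    low: 0.0
    high: 0.08
    dist: uniform
  wtp_per_qaly: 36289.0
  half_cycle_correction: no
  accrual: cycle_start
  chemo_duration_cycles: ~
  routine_cost_states:
  - pfs
  - pd
  ae_timing: one_time_entry
exchange_rate_cny_per_usd: 7.0848
trial:
  overall_pfs_hr: 0.52
curves:
  tc:
    os:
      family: weibull
      scale: 0.005008
      shape: 1.297713
    pfs:
      family: weibull
      scale: 0.07556
      shape: 0.95096
  chemo:
    os:
      family: weibull
      scale: 0.00106
      shape: 2.027554
    pfs:
      family: weibull
      scale: 0.034444
      shape: 1.615226
utilities:
  pfs:
    base: 0.65
    low: 0.52
    high: 0.78
    dist: beta
  pd:
    base: 0.52
    low: 0.416
    high: 0.624
    dist: beta
arms:
  tc:
    label: Tislelizumab plus chemotherapy
    drugs:
    - tislelizumab
    - gemcitabine
    - cisplatin
    post_discontinuation_rate:
      base: 0.52
      low: 0.416
      high: 0.624
      dist: beta
    ae_disutility:
      base: 0.007
      low: 0.0056
      high: 0.0084
      dist: beta
    ae_risks:
      lymphocyte_count_decreased:
        base: 0.107
        low: 0.086
        high: 0.128
        dist: beta
      platelet_count_decreased:
        base: 0.206
        low: 0.165
        high: 0.247
        dist: beta
      leukopenia:
        base: 0.206
        low: 0.165
        high: 0.247
        dist: beta
      neutropenia:
        base: 0.214
        low: 0.171
        high: 0.257
        dist: beta
      neutrophil_count_decreased:
        base: 0.275
        low: 0.22
        high: 0.33
        dist: beta
      anemia:
        base: 0.298
        low: 0.238
        high: 0.358
        dist: beta
      white_blood_cell_count_decreased:
        base: 0.313
        low: 0.25
        high: 0.376
        dist: beta
  chemo:
    label: Chemotherapy
    drugs:
    - gemcitabine
    - cisplatin
    post_discontinuation_rate:
      base: 0.72
      low: 0.576
      high: 0.864
      dist: beta
    ae_disutility:
      base: 0.0069
      low: 0.0055
      high: 0.0083
      dist: beta
    ae_risks:
      lymphocyte_count_decreased:
        base: 0.121
        low: 0.097
        high: 0.145
        dist: beta
      leukopenia:
        base: 0.159
        low: 0.127
        high: 0.191
        dist: beta
      neutropenia:
        base: 0.189
        low: 0.151
        high: 0.227
        dist: beta
      platelet_count_decreased:
        base: 0.258
        low: 0.206
        high: 0.31
        dist: beta
      anemia:
        base: 0.273
        low: 0.218
        high: 0.328
        dist: beta
      neutrophil_count_decreased:
        base: 0.348
        low: 0.278
        high: 0.418
        dist: beta
      white_blood_cell_count_decreased:
        base: 0.371
        low: 0.297
        high: 0.445
        dist: beta
costs:
  drugs:
    tislelizumab:
      base: 778.0
      low: 622.0
      high: 934.0
      dist: gamma
    gemcitabine:
      base: 39.0
      low: 31.0
      high: 47.0
      dist: gamma
    cisplatin:
      base: 31.0
      low: 25.0
      high: 37.0
      dist: gamma
    second_line:
      base: 77.0
      low: 62.0
      high: 92.0
      dist: gamma
  ae:
    leukopenia:
      base: 100.0
      low: 80.0
      high: 120.0
      dist: gamma
    lymphocyte_count_decreased:
      base: 100.0
      low: 80.0
      high: 120.0
      dist: gamma
    neutropenia:
      base: 466.0
      low: 373.0
      high: 559.0
      dist: gamma
    white_blood_cell_count_decreased:
      base: 466.0
      low: 373.0
      high: 559.0
      dist: gamma
    neutrophil_count_decreased:
      base: 466.0
      low: 373.0
      high: 559.0
      dist: gamma
    anemia:
      base: 537.0
      low: 430.0
      high: 644.0
      dist: gamma
    platelet_count_decreased:
      base: 3588.0
      low: 2870.0
      high: 4306.0
      dist: gamma
  routine:
    laboratory:
      base: 97.0
      low: 78.0
      high: 116.0
      dist: gamma
    tumor_imaging:
      base: 208.0
      low: 166.0
      high: 250.0
      dist: gamma
    administration:
      base: 48.0
      low: 38.0
      high: 58.0
      dist: gamma
  best_supportive_care:
    base: 142.0
    low: 114.0
    high: 170.0
    dist: gamma
  terminal_care:
    base: 1833.0
    low: 1466.0
    high: 2200.0
    dist: gamma
subgroups:
- label: Age < 65
  pfs_hr: 0.45
  ci:
  - 0.33
  - 0.62
- label: Male
  pfs_hr: 0.51
  ci:
  - 0.36
  - 0.71
- label: Female
  pfs_hr: 0.44
  ci:
  - 0.23
  - 0.83
- label: ECOG PS 0
  pfs_hr: 0.46
  ci:
  - 0.28
  - 0.74
- label: ECOG PS 1
  pfs_hr: 0.51
  ci:
  - 0.35
  - 0.75
- label: Never smoker
  pfs_hr: 0.38
  ci:
  - 0.25
  - 0.58
- label: Former smoker
  pfs_hr: 0.66
  ci:
  - 0.41
  - 1.06
- label: Primary metastatic
  pfs_hr: 0.53
  ci:
  - 0.39
  - 0.71
- label: Liver metastases
  pfs_hr: 0.48
  ci:
  - 0.31
  - 0.74
- label: No liver metastases
  pfs_hr: 0.53
  ci:
  - 0.35
  - 0.8
- label: EBV DNA < 500 IU/mL
  pfs_hr: 0.55
  ci:
  - 0.28
  - 1.07
- label: EBV DNA >= 500 IU/mL
  pfs_hr: 0.46
  ci:
  - 0.32
  - 0.64
- label: PD-L1 < 10%
  pfs_hr: 0.46
  ci:
  - 0.26
  - 0.81
- label: PD-L1 >= 10%
  pfs_hr: 0.47
  ci:
  - 0.32
  - 0.68
scenario:
  copayment:
    gemcitabine: 0.2
    cisplatin: 0.0
    capecitabine: 0.05
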
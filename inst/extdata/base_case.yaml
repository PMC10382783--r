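cost_year: 2013 hospital tariffs; salary-scale year as published
reference:
  display: SC
  p_error:
    mean: 0.653
    sd: 0.2
    'n': 101
  error_cost:
    mean: 1091.119999999999891
    sd: 220.919999999999987
    ci:
    - 702.509999999999991
    - 1551.0
    'n': 1000
  labour_cost:
    mean: 37.210000000000001
    ci:
    - 29.18
    - 47.390000000000001
  utility_decrement:
    mean: -0.02906349626
    sd: 0.072
    'n': 66
intervention:
  display: PACT
  p_error:
    mean: 0.139
    sd: 0.2
    'n': 108
  error_cost:
    mean: 638.730000000000018
    sd: 205.759999999999991
    ci:
    - 248.409999999999997
    - 1074.170000000000073
    'n': 1000
  labour_cost:
    mean: 86.700000000000003
    ci:
    - 58.840000000000003
    - 119.769999999999996
  utility_decrement:
    mean: -0.023469269
    sd: 0.075
    'n': 15
dsa:
  relative_variation: 0.2
psa:
  iterations: 1000
  probability_sd: 0.2
  bootstrap_reps: 1000
  overrides:
    reference.p_error:
      family: beta
      alpha: 372.95999999999998
      beta: 198.189999999999998
    intervention.p_error:
      family: beta
      alpha: 44.780000000000001
      beta: 277.360000000000014
    reference.error_cost:
      family: gamma
      alpha: 24393.590000000000146
      beta: 0.04473
    intervention.error_cost:
      family: gamma
      alpha: 9636.579999999999927
      beta: 0.06628
    reference.labour_cost:
      family: gamma
      alpha: 59903.580000000001746
      beta: 0.00062
    intervention.labour_cost:
      family: gamma
      alpha: 30197.419999999998254
      beta: 0.00287
    reference.utility_decrement:
      family: one_minus_gamma
      alpha: 13279.819999999999709
      beta: 8.000000000000001e-05
    intervention.utility_decrement:
      family: one_minus_gamma
      alpha: 2828.559999999999945
      beta: 0.00036
wtp:
  from: 0.0
  to: 50000.0
  by: 1000.0
labour:
  calendar:
    hours_per_week: 37.0
    leave_days: 24.0
    public_holidays: 9.0
    break_hours_per_day: 1.0
    days_per_year: 365.25
  reference:
    salary:
      annual_gross: 48960.0
      prsi_rate: 0.1075
      pension_rate: 0.131
      overhead_rate: 0.4
    mean_minutes: 40.600000000000001
  intervention:
    salary:
      annual_gross: 64489.5
      prsi_rate: 0.1075
      pension_rate: 0.131
      overhead_rate: 0.4
    mean_minutes: 72.799999999999997
cohort:
  reference:
    arm_label: reference
    n_patients: 101
    p_error: 0.653
    time_mean: 40.600000000000001
    time_sd: 29.170000000000002
    cost_mean: 1091.119999999999891
    cost_sd: 1091.119999999999891
    decrement_mean: -0.02906349626
    decrement_sd: 0.072
  intervention:
    arm_label: intervention
    n_patients: 108
    p_error: 0.139
    time_mean: 72.799999999999997
    time_sd: 52.469999999999999
    cost_mean: 638.730000000000018
    cost_sd: 638.730000000000018
    decrement_mean: -0.023469269
    decrement_sd: 0.075
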
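prevalence: 0.17
start_split_abused:
  U: 0.964
  A: 0.003
  I: 0.033
transitions:
  control:
    'N':
      U: 0.0037
      D: 0.00551
    U:
      'N': 0.05
      A: 0.0005
      I: 0.0027
      D: 0.00554
    A:
      'N': 0.1408
      D: 0.00554
    I:
      'N': 0.0781
      D: 0.00554
  intervention:
    'N':
      U: 0.0037
      D: 0.00551
    U:
      'N': 0.05
      A: 0.0056
      I: 0.0109
      D: 0.00554
    A:
      'N': 0.1408
      D: 0.00554
    I:
      'N': 0.0781
      D: 0.00554
utilities:
  'N': 0.85
  U: 0.63
  A: 0.65
  I: 0.63
  D: 0.0
costs:
  abuse_per_cycle: 2043.0
  weight_seeing: 1.0
  weight_not_seeing: 1.0
  intervention_per_woman_cycle: 0.46
  referral_once: 312.0
  nhs_cost_share: 0.286
settings:
  discount_rate_annual: 0.035
  cycle_length_years: 0.5
  n_cycles: 20
  wtp: 20000.0
  cohort_size: 10000.0
  n_psa: 1000
  rng_seed: 1234
options:
  stay_mode: complement
  charge_initial_advocates: no
  dirichlet_mode: element_beta
uncertainty:
  prevalence:
    family: beta
    base: 0.17
    low: 0.147
    high: 0.194
  start_seeing:
    family: uniform
    base: 0.003
    low: 0.0
    high: 0.0066
  start_not_seeing:
    family: uniform
    base: 0.033
    low: 0.0
    high: 0.066
  tp_N_U:
    family: dirichlet_row_member
    base: 0.0037
    low: 0.0004
    high: 0.0106
  tp_N_D:
    family: dirichlet_row_member
    base: 0.00551
    low: 0.001
    high: 0.0136
  tp_control_U_N:
    family: dirichlet_row_member
    base: 0.05
    low: 0.045
    high: 0.0553
  tp_control_U_I:
    family: dirichlet_row_member
    base: 0.0027
    low: 0.0016
    high: 0.004
  tp_control_U_A:
    family: dirichlet_row_member
    base: 0.0005
    low: 0.0001
    high: 0.0011
  tp_control_U_D:
    family: dirichlet_row_member
    base: 0.00554
    low: 0.0039
    high: 0.0074
  tp_intervention_U_N:
    family: dirichlet_row_member
    base: 0.05
    low: 0.045
    high: 0.0553
  tp_intervention_U_I:
    family: dirichlet_row_member
    base: 0.0109
    low: 0.0086
    high: 0.0135
  tp_intervention_U_A:
    family: dirichlet_row_member
    base: 0.0056
    low: 0.004
    high: 0.0076
  tp_intervention_U_D:
    family: dirichlet_row_member
    base: 0.00554
    low: 0.0039
    high: 0.0074
  tp_A_N:
    family: dirichlet_row_member
    base: 0.1408
    low: 0.0707
    high: 0.2301
  tp_A_D:
    family: dirichlet_row_member
    base: 0.00554
    low: 0.0
    high: 0.0309
  tp_I_N:
    family: dirichlet_row_member
    base: 0.0781
    low: 0.0136
    high: 0.1912
  tp_I_D:
    family: dirichlet_row_member
    base: 0.00554
    low: 0.0
    high: 0.0438
  util_N:
    family: beta
    base: 0.85
    low: 0.84
    high: 0.86
  util_U:
    family: beta
    base: 0.63
    low: 0.503
    high: 0.749
  util_A:
    family: beta
    base: 0.65
    low: 0.518
    high: 0.771
  util_I:
    family: beta
    base: 0.63
    low: 0.503
    high: 0.749
  cost_intervention:
    family: gamma
    base: 0.46
    low: 0.01
    high: 1.69
  cost_referral:
    family: gamma
    base: 312.0
    low: 8.0
    high: 1127.0
  cost_abuse:
    family: gamma
    base: 2043.0
    low: 52.0
    high: 7536.0
  cost_weight_seeing:
    family: gamma
    base: 1.0
    low: 0.75
    high: 1.25
  cost_weight_not_seeing:
    family: gamma
    base: 1.0
    low: 0.9
    high: 1.1
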
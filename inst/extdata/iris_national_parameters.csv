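"parameter","base","low","high","family","source"
"prevalence",0.17,0.147,0.194,"beta","cross-sectional general-practice survey"
"start_seeing",0.003,0,0.0066,"uniform","model calibration"
"start_not_seeing",0.033,0,0.066,"uniform","model calibration"
"tp_N_U",0.0037,4e-04,0.0106,"dirichlet_row_member","model calibration"
"tp_N_D",0.00551,0.001,0.0136,"dirichlet_row_member","national mortality statistics"
"tp_control_U_N",0.05,0.045,0.0553,"dirichlet_row_member","model calibration"
"tp_control_U_I",0.0027,0.0016,0.004,"dirichlet_row_member","programme monitoring data"
"tp_control_U_A",5e-04,1e-04,0.0011,"dirichlet_row_member","programme monitoring data"
"tp_control_U_D",0.00554,0.0039,0.0074,"dirichlet_row_member","advocacy systematic review"
"tp_intervention_U_N",0.05,0.045,0.0553,"dirichlet_row_member","model calibration"
"tp_intervention_U_I",0.0109,0.0086,0.0135,"dirichlet_row_member","programme monitoring data"
"tp_intervention_U_A",0.0056,0.004,0.0076,"dirichlet_row_member","programme monitoring data"
"tp_intervention_U_D",0.00554,0.0039,0.0074,"dirichlet_row_member","advocacy systematic review"
"tp_A_N",0.1408,0.0707,0.2301,"dirichlet_row_member","advocacy systematic review"
"tp_A_D",0.00554,0,0.0309,"dirichlet_row_member","advocacy systematic review"
"tp_I_N",0.0781,0.0136,0.1912,"dirichlet_row_member","advocacy systematic review"
"tp_I_D",0.00554,0,0.0438,"dirichlet_row_member","advocacy systematic review"
"util_N",0.85,0.84,0.86,"beta","population utility norms"
"util_U",0.63,0.503,0.749,"beta","abuse health-state valuation"
"util_A",0.65,0.518,0.771,"beta","abuse health-state valuation"
"util_I",0.63,0.503,0.749,"beta","abuse health-state valuation"
"cost_intervention",0.46,0.01,1.69,"gamma","programme budgets"
"cost_referral",312,8,1127,"gamma","programme budgets"
"cost_abuse",2043,52,7536,"gamma","national cost-of-abuse report"
"cost_weight_seeing",1,0.75,1.25,"gamma","assumption"
"cost_weight_not_seeing",1,0.9,1.1,"gamma","assumption"
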
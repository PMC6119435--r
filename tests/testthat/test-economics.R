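# Discounting, accrual, perspectives and incremental comparison.

test_that("discount factors follow the annual rate over elapsed years", {
  expect_identical(discount_factor(0, 0.035, 0.5), 1)
  expect_equal(discount_factor(2, 0.035, 0.5), 1 / 1.035)
  expect_equal(discount_factor(20, 0.035, 0.5), 1.035^-10)
  expect_equal(discount_factor(3, 0, 0.5), 1)
  expect_error(discount_factor(1, -0.01, 0.5), "rate")
})

test_that("a frozen healthy cohort accrues exactly the undiscounted horizon", {
  p <- frozen_params(discount = 0)
  p$utilities[living_states()] <- 1
  tr <- run_cohort(build_transition_matrix(p, "control"),
                   initial_distribution(p), p$settings$n_cycles)
  # 20 half-year cycles at utility 1: 10 QALYs
  expect_equal(accrue_qalys(tr, p), 10)

  p$utilities[living_states()] <- 0
  expect_equal(accrue_qalys(tr, p), 0)
})

test_that("programme cost alone equals the per-cycle fee times the horizon", {
  p <- frozen_params(discount = 0)
  p$costs$abuse_per_cycle <- 0
  p$costs$referral_once <- 0
  p$costs$intervention_per_woman_cycle <- 0.46
  tr <- run_cohort(build_transition_matrix(p, "intervention"),
                   initial_distribution(p), p$settings$n_cycles)
  expect_equal(as.numeric(accrue_costs(tr, p, "intervention", "societal")),
               0.46 * 20)
  # the control arm never pays the programme
  expect_equal(as.numeric(accrue_costs(tr, p, "control", "societal")), 0)
})

test_that("zero costs accrue zero under both perspectives", {
  p <- toy_models()$zero_cost$params
  for (arm in c("control", "intervention"))
    for (persp in c("societal", "nhs"))
      expect_equal(as.numeric(run_arm(p, arm, persp)[["cost"]]), 0)
})

test_that("referral costs follow entrants, not initial occupants, unless toggled", {
  p <- default_iris_parameters()
  tr <- run_cohort(build_transition_matrix(p, "control"),
                   initial_distribution(p), p$settings$n_cycles)
  base <- attr(accrue_costs(tr, p, "control", "societal"), "components")

  p2 <- p
  p2$options$charge_initial_advocates <- TRUE
  toggled <- attr(accrue_costs(tr, p2, "control", "societal"), "components")
  expect_equal(toggled[["referral"]] - base[["referral"]],
               312 * initial_distribution(p)[["A"]])

  # entrants into the seeing-advocate state come from U only
  d <- discount_factor(1:20, 0.035, 0.5)
  expect_equal(base[["referral"]], 312 * sum(tr$entrants[, "A"] * d))
})

test_that("the NHS perspective scales only the state-cost stream", {
  p <- default_iris_parameters()
  tr <- run_cohort(build_transition_matrix(p, "intervention"),
                   initial_distribution(p), p$settings$n_cycles)
  soc <- attr(accrue_costs(tr, p, "intervention", "societal"), "components")
  nhs <- attr(accrue_costs(tr, p, "intervention", "nhs"), "components")
  expect_equal(nhs[["state"]], soc[["state"]] * p$costs$nhs_cost_share)
  expect_equal(nhs[["referral"]], soc[["referral"]])
  expect_equal(nhs[["programme"]], soc[["programme"]])
})

test_that("the NHS cost share back-solves in closed form", {
  p <- default_iris_parameters()
  ctrl_soc <- run_arm(p, "control", "societal")
  comp <- attr(accrue_costs(attr(ctrl_soc, "trace"), p, "control", "societal"),
               "components")

  # limit cases: societal total implies share 1; referral floor implies 0
  expect_equal(derive_nhs_cost_share(p, ctrl_soc[["cost"]]), 1)
  expect_equal(derive_nhs_cost_share(p, comp[["referral"]]), 0)
  expect_error(derive_nhs_cost_share(p, comp[["referral"]] * 0.5), "floor")

  # any attainable target is reproduced exactly by the derived share
  target <- 1232
  share <- derive_nhs_cost_share(p, target)
  p2 <- set_param_value(p, "nhs_cost_share", share)
  expect_equal(run_arm(p2, "control", "nhs")[["cost"]], target)
  expect_gt(share, 0); expect_lt(share, 1)
})

test_that("comparisons classify dominance and honour the NMB identity", {
  eq <- compare_arms(c(100, 5), c(100, 5), wtp = 20000)
  expect_equal(eq$incremental_cost, 0)
  expect_equal(eq$nmb, 0)
  expect_true(is.na(eq$icer) && is.na(eq$dominance))

  dom <- compare_arms(c(100, 5), c(86, 5.001), wtp = 20000)
  expect_identical(dom$dominance, "intervention dominates control")
  expect_equal(dom$nmb, 20000 * 0.001 + 14)
  expect_true(is.na(dom$icer))

  rev <- compare_arms(c(86, 5.001), c(100, 5), wtp = 20000)
  expect_identical(rev$dominance, "control dominates intervention")

  icer <- compare_arms(c(100, 5), c(106, 5.001), wtp = 20000)
  expect_true(is.na(icer$dominance))
  expect_equal(icer$icer, 6 / 0.001)

  # NMB identity to machine precision on random magnitudes
  set.seed(4)
  for (i in 1:50) {
    c0 <- runif(1, 0, 1e4); c1 <- runif(1, 0, 1e4)
    q0 <- runif(1, 0, 10); q1 <- runif(1, 0, 10)
    w <- runif(1, 0, 5e4)
    cmp <- compare_arms(c(c0, q0), c(c1, q1), w)
    expect_identical(cmp$nmb, w * (q1 - q0) - (c1 - c0))
  }
})

test_that("identical arms produce exactly zero increments end to end", {
  toy <- toy_models()$equal_arms
  econ <- run_base_case(toy$params)
  expect_identical(econ$incremental_cost, 0)
  expect_identical(econ$incremental_qaly, 0)
  expect_identical(econ$nmb, 0)

  # removing identification and programme/referral costs equalises the arms
  p <- default_iris_parameters()
  for (id in c("tp_control_U_A", "tp_control_U_I",
               "tp_intervention_U_A", "tp_intervention_U_I"))
    p <- set_param_value(p, id, 0)
  p$costs$intervention_per_woman_cycle <- 0
  p$costs$referral_once <- 0
  econ2 <- run_base_case(p)
  expect_identical(econ2$incremental_cost, 0)
  expect_identical(econ2$incremental_qaly, 0)
})

test_that("discounting harder never increases accrued costs or QALYs", {
  for (seed in c(5, 17)) {
    p <- random_parameter_set(synthetic_spec(seed = seed))
    rates <- c(0, 0.015, 0.035, 0.08)
    res <- vapply(rates, function(r) {
      p$settings$discount_rate_annual <- r
      run_arm(p, "intervention", "societal")
    }, numeric(2))
    expect_true(all(diff(res["cost", ]) <= 1e-9))
    expect_true(all(diff(res["qaly", ]) <= 1e-9))
  }
})

test_that("per-woman results are independent of the nominal cohort size", {
  p <- default_iris_parameters()
  base <- run_base_case(p)
  p$settings$cohort_size <- 20000
  expect_identical(run_base_case(p)$incremental_cost, base$incremental_cost)
  expect_identical(run_base_case(p)$control, base$control)
})
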
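# Distribution fitting, one-way and probabilistic sensitivity analysis.

test_that("fixed and degenerate specs sample as point masses", {
  fit <- fit_distribution(dist_spec("fixed", 0.46))
  expect_identical(sample_distribution(fit, 5), rep(0.46, 5))
  fit2 <- fit_distribution(dist_spec("beta", 0.5, 0.5, 0.5))
  expect_identical(fit2$family, "fixed")
})

test_that("beta fits preserve the mean and the stated 95% limits", {
  fit <- fit_distribution(dist_spec("beta", 0.85, 0.840, 0.860))
  expect_equal(fitted_mean <- fit$shape1 / (fit$shape1 + fit$shape2),
               0.85, tolerance = 1e-6)
  # quantiles recovered by numeric quadrature, independently of qbeta
  q025 <- quadrature_beta_quantile(0.025, fit$shape1, fit$shape2)
  q975 <- quadrature_beta_quantile(0.975, fit$shape1, fit$shape2)
  expect_equal(q025, 0.840, tolerance = 0.002)
  expect_equal(q975, 0.860, tolerance = 0.002)
})

test_that("gamma fits preserve the mean of heavily skewed cost limits", {
  fit <- fit_distribution(dist_spec("gamma", 2043, 52, 7536))
  expect_equal(fit$shape * fit$scale, 2043, tolerance = 0.1)
  sd <- sqrt(fit$shape) * fit$scale
  expect_equal(sd, (7536 - 52) / 3.92, tolerance = 0.1)
})

test_that("infeasible beta moments are rejected with the parameter name", {
  expect_error(
    fit_distribution(dist_spec("beta", 0.001, 0, 0.9), id = "util_X"),
    "util_X")
})

test_that("joint draws are deterministic given the RNG state and always valid", {
  p <- default_iris_parameters()
  set.seed(7); d1 <- sample_parameter_set(p)
  set.seed(7); d2 <- sample_parameter_set(p)
  expect_equal(unclass(d1), unclass(d2), tolerance = 0)

  set.seed(11)
  for (i in 1:25) {
    d <- sample_parameter_set(p)
    expect_length(validate_parameters(d), 0)
  }
})

test_that("drawn parameter means converge to the fitted means", {
  p <- default_iris_parameters()
  fit <- fit_distribution(p$uncertainty$prevalence)
  set.seed(21)
  x <- sample_distribution(fit, 10000)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.17), 3 * se)
})

test_that("all-fixed uncertainty collapses draws to the base case", {
  p <- default_iris_parameters()
  p$uncertainty <- lapply(p$uncertainty, function(sp) dist_spec("fixed", sp$base))
  set.seed(3)
  d <- sample_parameter_set(p)
  attr(d, "audit") <- NULL
  expect_equal(d, p, tolerance = 0)

  psa <- run_psa(p, n_sim = 10, seed = 5)
  base <- run_base_case(p)
  expect_true(all(abs(psa$draws$inc_cost - base$incremental_cost) < 1e-12))
  expect_true(psa$fractions[["cost_effective"]] %in% c(0, 1))
})

test_that("the tornado reproduces the base NMB at degenerate ranges and sorts by span", {
  p <- default_iris_parameters()
  base_nmb <- run_base_case(p)$nmb
  tor <- owsa(p, overrides = list(prevalence = c(0.17, 0.17)))
  row <- tor[tor$parameter == "prevalence", ]
  expect_equal(row$nmb_at_low, base_nmb)
  expect_equal(row$nmb_at_high, base_nmb)
  expect_equal(attr(tor, "base_nmb"), base_nmb)
  spans <- tor$span[tor$feasible]
  expect_true(all(diff(spans) <= 1e-9))
})

test_that("limits that break row feasibility are flagged, not clamped", {
  p <- default_iris_parameters()
  p$uncertainty$tp_control_U_N <- dist_spec("dirichlet_row_member",
                                            0.05, 0.045, 0.999)
  tor <- owsa(p)
  row <- tor[tor$parameter == "tp_control_U_N", ]
  expect_false(row$feasible)
  expect_true(is.na(row$nmb_at_high))
  expect_false(is.na(row$nmb_at_low))
})

test_that("monotone parameters bracket the base NMB from both sides", {
  p <- default_iris_parameters()
  base_nmb <- run_base_case(p)$nmb
  tor <- owsa(p)
  # the control recovery probability has a monotone decreasing NMB response
  row <- tor[tor$parameter == "tp_control_U_N", ]
  expect_gt(row$nmb_at_low, base_nmb)
  expect_lt(row$nmb_at_high, base_nmb)
})

test_that("the PSA is bit-reproducible and its summaries match its draws", {
  p <- default_iris_parameters()
  a <- run_psa(p, n_sim = 60, seed = 17)
  b <- run_psa(p, n_sim = 60, seed = 17)
  expect_identical(a$draws, b$draws)
  expect_identical(a$fractions, b$fractions)
  expect_identical(a$ceac, b$ceac)

  with(a$draws, {
    expect_equal(a$fractions[["dominant"]], mean(inc_cost < 0 & inc_qaly > 0))
    expect_equal(a$fractions[["dominated"]], mean(inc_cost > 0 & inc_qaly < 0))
    expect_equal(a$fractions[["cost_effective"]], mean(nmb > 0))
  })
  expect_lte(a$fractions[["dominant"]] + a$fractions[["dominated"]], 1)
  expect_identical(a$draws$nmb,
                   a$wtp * a$draws$inc_qaly - a$draws$inc_cost)
})

test_that("shrinking all variances collapses the PSA onto the base case", {
  p <- default_iris_parameters()
  eps <- 1e-4  # variance scale; sd scale is its square root
  p$uncertainty <- lapply(p$uncertainty, function(sp) {
    if (sp$low == sp$high) return(sp)
    dist_spec(sp$family,
              sp$base,
              sp$base - sqrt(eps) * (sp$base - sp$low),
              sp$base + sqrt(eps) * (sp$high - sp$base))
  })
  base <- run_base_case(p)
  psa <- run_psa(p, n_sim = 200, seed = 29)
  se_c <- sd(psa$draws$inc_cost) / sqrt(200)
  se_q <- sd(psa$draws$inc_qaly) / sqrt(200)
  expect_lt(abs(mean(psa$draws$inc_cost) - base$incremental_cost), 3 * se_c)
  expect_lt(abs(mean(psa$draws$inc_qaly) - base$incremental_qaly), 3 * se_q)
})

test_that("the CEAC counts positive-NMB simulations and is monotone for QALY-gaining draws", {
  hand <- data.frame(inc_cost = c(-10, 5, 20, -3, 8),
                     inc_qaly = c(0.001, 0.001, -0.002, -0.001, 0.0005))
  curve <- ceac(hand, wtp_grid = c(0, 10000, 20000))
  # by hand enumeration of wtp * dq - dc > 0 per simulation
  expect_equal(curve$probability, c(2, 2, 3) / 5)

  all_gain <- data.frame(inc_cost = c(-5, -1), inc_qaly = c(0.01, 0.02))
  expect_true(all(ceac(all_gain)$probability == 1))

  p <- default_iris_parameters()
  psa <- run_psa(p, n_sim = 150, seed = 31)
  gain <- psa$draws[psa$draws$inc_qaly >= 0, ]
  expect_true(all(diff(ceac(gain)$probability) >= 0))

  expect_error(ceac(hand, numeric(0)), "wtp_grid")
})

test_that("percentile intervals follow the linear-interpolation convention", {
  expect_equal(percentile_interval(1:1000),
               c(low = 25.975, high = 975.025))
  expect_identical(percentile_interval(rep(7, 10)), c(low = 7, high = 7))
  set.seed(8)
  x <- rnorm(500)
  expect_identical(percentile_interval(x), percentile_interval(sample(x)))
  expect_error(percentile_interval(1), "two samples")
})

test_that("the true-Dirichlet row mode also yields valid, mean-centred draws", {
  p <- default_iris_parameters()
  p$options$dirichlet_mode <- "dirichlet"
  set.seed(19)
  draws <- replicate(400, {
    d <- sample_parameter_set(p)
    expect_length(validate_parameters(d), 0)
    param_value(d, "tp_control_U_N")
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.05), 3 * se + 1e-4)
})
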
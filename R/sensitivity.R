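#' One-way (tornado) sensitivity analysis
#'
#' Every parameter with a non-degenerate uncertainty specification is set in
#' turn to its lower and its upper 95% limit, holding everything else at
#' base, and the full deterministic pipeline (both arms, societal
#' perspective) is re-run to record the net monetary benefit at each limit.
#' Transition-row members are varied with the stay probability re-derived as
#' the complement. A limit that leaves a transition row with exits summing
#' to one or more is flagged infeasible rather than silently clamped.
#'
#' @param params An `iris_parameters` object.
#' @param wtp Willingness to pay per QALY; defaults to the configured value.
#' @param overrides Optional named list mapping parameter ids to
#'   `c(low, high)` ranges that replace the stored limits (used, e.g., to
#'   vary a transition over a narrower policy-relevant band).
#' @return Data frame of class `iris_tornado` with columns `parameter`,
#'   `low`, `high`, `nmb_at_low`, `nmb_at_high`, `span`, `feasible`, sorted
#'   by span descending; the base-case NMB is attached as attribute
#'   `base_nmb`.
#' @export
#' @examples
#' tor <- owsa(default_iris_parameters())
#' head(tor, 3)
owsa <- function(params, wtp = params$settings$wtp, overrides = NULL) {
  base <- run_base_case(params, "societal", wtp)

  nmb_at <- function(id, value) {
    p2 <- set_param_value(params, id, value)
    bad <- validate_parameters(p2)
    if (length(bad)) return(NA_real_)
    run_base_case(p2, "societal", wtp)$nmb
  }

  ids <- names(params$uncertainty)
  rows <- lapply(ids, function(id) {
    spec <- params$uncertainty[[id]]
    rng <- if (!is.null(overrides[[id]])) overrides[[id]] else c(spec$low, spec$high)
    if (is.null(overrides[[id]]) && is_degenerate_spec(spec)) return(NULL)
    lo <- nmb_at(id, rng[1])
    hi <- nmb_at(id, rng[2])
    data.frame(parameter = id, low = rng[1], high = rng[2],
               nmb_at_low = lo, nmb_at_high = hi,
               span = abs(hi - lo),
               feasible = !is.na(lo) && !is.na(hi))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(parameter = character(), low = numeric(),
                      high = numeric(), nmb_at_low = numeric(),
                      nmb_at_high = numeric(), span = numeric(),
                      feasible = logical())
  }
  out <- out[order(out$span, decreasing = TRUE, na.last = TRUE), ]
  rownames(out) <- NULL
  structure(out, base_nmb = base$nmb, wtp = wtp,
            class = c("iris_tornado", "data.frame"))
}

#' Draw one joint parameter set from the fitted uncertainty distributions
#'
#' All parameters are sampled independently from their method-of-moments
#' fits (see [fit_distribution()]). Rows shared between the two arms (the
#' not-abused and identified-state rows) receive a single draw applied to
#' both arms; the arm-specific abused-unidentified rows are drawn
#' separately. After sampling, each transition row is re-closed through the
#' stay complement; if a row's drawn exits sum to one or more they are
#' rescaled to sum 0.999 and the repair is recorded in the draw's
#' `audit` attribute. Under `options$dirichlet_mode = "dirichlet"` the
#' transition rows are instead drawn from a Dirichlet whose concentration is
#' least-squares fitted to the per-element 95% limits.
#'
#' Uses the current RNG state; seed control belongs to the caller.
#'
#' @param params An `iris_parameters` object.
#' @param fits Optional pre-computed list of fitted distributions (an
#'   optimisation for repeated calls); by default fitted on the fly.
#' @return An `iris_parameters` draw that passes [validate_parameters()],
#'   with attribute `audit` listing any repaired rows.
#' @export
#' @examples
#' set.seed(1)
#' draw <- sample_parameter_set(default_iris_parameters())
#' draw$prevalence
sample_parameter_set <- function(params, fits = NULL) {
  if (is.null(fits)) fits <- fit_all(params)
  audit <- character()
  draw <- params

  dirichlet <- identical(params$options$dirichlet_mode, "dirichlet")
  row_ids <- transition_row_ids()
  scalar_ids <- setdiff(names(params$uncertainty), unlist(row_ids))

  for (id in scalar_ids)
    draw <- set_param_value(draw, id, sample_distribution(fits[[id]], 1))

  for (row in row_ids) {
    vals <- if (dirichlet) {
      sample_dirichlet_row(params, row)
    } else {
      vapply(row, function(id) sample_distribution(fits[[id]], 1), numeric(1))
    }
    names(vals) <- row
    total <- sum(vals)
    if (total >= 1) {
      vals <- vals * (0.999 / total)
      audit <- c(audit, sprintf(
        "row {%s}: drawn exits summed to %.4f; rescaled to 0.999",
        paste(row, collapse = ", "), total))
    }
    for (id in row) draw <- set_param_value(draw, id, unname(vals[id]))
  }

  # start split: keep the identified fractions feasible as a pair
  si <- draw$start_split_abused[["A"]] + draw$start_split_abused[["I"]]
  if (si >= 1) {
    draw <- set_param_value(draw, "start_seeing",
                            draw$start_split_abused[["A"]] * 0.999 / si)
    draw <- set_param_value(draw, "start_not_seeing",
                            draw$start_split_abused[["I"]] * 0.999 / si)
    audit <- c(audit, "start split: identified fractions rescaled to 0.999")
  }

  structure(draw, audit = audit)
}

# transition ids grouped by matrix row (the unit that must stay sub-stochastic)
transition_row_ids <- function() {
  list(N = c("tp_N_U", "tp_N_D"),
       U_control = c("tp_control_U_N", "tp_control_U_A",
                     "tp_control_U_I", "tp_control_U_D"),
       U_intervention = c("tp_intervention_U_N", "tp_intervention_U_A",
                          "tp_intervention_U_I", "tp_intervention_U_D"),
       A = c("tp_A_N", "tp_A_D"),
       I = c("tp_I_N", "tp_I_D"))
}

fit_all <- function(params) {
  out <- lapply(names(params$uncertainty), function(id)
    fit_distribution(params$uncertainty[[id]], id))
  names(out) <- names(params$uncertainty)
  out
}

# True-Dirichlet row draw: the full row mean is (exits, stay-complement);
# a single concentration is fitted by least squares so that the implied
# beta marginals of the exits best match their printed 95% limits.
sample_dirichlet_row <- function(params, row) {
  means <- vapply(row, function(id) params$uncertainty[[id]]$base, numeric(1))
  stay <- 1 - sum(means)
  full <- c(means, stay)
  obj <- function(log_a0) {
    a0 <- exp(log_a0)
    sum(vapply(seq_along(row), function(i) {
      sp <- params$uncertainty[[row[i]]]
      a <- a0 * means[i]; b <- a0 * (1 - means[i])
      (stats::qbeta(0.025, a, b) - sp$low)^2 +
        (stats::qbeta(0.975, a, b) - sp$high)^2
    }, numeric(1)))
  }
  a0 <- exp(stats::optimize(obj, c(log(10), log(1e7)))$minimum)
  g <- stats::rgamma(length(full), shape = a0 * full, rate = 1)
  d <- g / sum(g)
  d[seq_along(row)]
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_sim` joint parameter sets, runs both arms per draw under the
#' societal perspective, and records the incremental cost and QALYs. The
#' result carries the dominance fractions, the fraction cost-effective at
#' the configured willingness to pay, percentile uncertainty intervals and
#' the cost-effectiveness acceptability curve over a WTP grid.
#'
#' @param params An `iris_parameters` object.
#' @param n_sim Number of simulations (defaults to the configured
#'   `settings$n_psa`).
#' @param seed RNG seed making the analysis fully reproducible (defaults to
#'   the configured `settings$rng_seed`).
#' @param wtp_grid WTP grid for the acceptability curve (default GBP 0 to
#'   50,000 in steps of 1,000).
#' @return An object of class `iris_psa`: a list with `draws` (data frame
#'   of per-simulation `inc_cost`, `inc_qaly`, `nmb`), the summary
#'   `fractions`, `intervals` (95% percentile intervals), `ceac` and the
#'   seed used.
#' @export
#' @examples
#' psa <- run_psa(default_iris_parameters(), n_sim = 25, seed = 1)
#' psa$fractions
run_psa <- function(params, n_sim = params$settings$n_psa,
                    seed = params$settings$rng_seed,
                    wtp_grid = seq(0, 50000, by = 1000)) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  set.seed(seed)
  fits <- fit_all(params)
  inc_cost <- numeric(n_sim)
  inc_qaly <- numeric(n_sim)
  n_repaired <- 0L
  for (i in seq_len(n_sim)) {
    draw <- sample_parameter_set(params, fits)
    if (length(attr(draw, "audit"))) n_repaired <- n_repaired + 1L
    ctrl <- run_arm(draw, "control", "societal")
    intv <- run_arm(draw, "intervention", "societal")
    inc_cost[i] <- intv[["cost"]] - ctrl[["cost"]]
    inc_qaly[i] <- intv[["qaly"]] - ctrl[["qaly"]]
  }
  wtp <- params$settings$wtp
  nmb <- wtp * inc_qaly - inc_cost
  draws <- data.frame(sim = seq_len(n_sim), inc_cost = inc_cost,
                      inc_qaly = inc_qaly, nmb = nmb)

  fractions <- c(
    dominant = mean(inc_cost < 0 & inc_qaly > 0),
    dominated = mean(inc_cost > 0 & inc_qaly < 0),
    cost_effective = mean(nmb > 0))

  pint <- function(x) if (length(x) < 2) c(low = x, high = x) else percentile_interval(x)
  intervals <- rbind(
    inc_cost = pint(inc_cost),
    inc_qaly = pint(inc_qaly),
    nmb = pint(nmb))

  structure(list(
    draws = draws,
    fractions = fractions,
    intervals = intervals,
    ceac = ceac(draws, wtp_grid),
    wtp = wtp,
    seed = seed,
    n_repaired = n_repaired), class = "iris_psa")
}

#' @export
print.iris_psa <- function(x, ...) {
  n <- nrow(x$draws)
  cat(sprintf("Probabilistic sensitivity analysis: %d simulations (seed %d)\n",
              n, x$seed))
  cat(sprintf("  intervention dominant in %.1f%%, dominated in %.1f%% of simulations\n",
              100 * x$fractions[["dominant"]], 100 * x$fractions[["dominated"]]))
  cat(sprintf("  cost-effective at WTP %s in %.1f%% of simulations\n",
              format(x$wtp, big.mark = ","),
              100 * x$fractions[["cost_effective"]]))
  cat("  95% percentile intervals:\n")
  print(round(x$intervals, 4))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of simulations whose net
#' monetary benefit is strictly positive at that threshold.
#'
#' @param psa An `iris_psa` object, or a data frame with columns `inc_cost`
#'   and `inc_qaly`.
#' @param wtp_grid Non-empty vector of non-negative WTP values.
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  if (!length(wtp_grid) || any(wtp_grid < 0))
    stop("wtp_grid must be non-empty and non-negative")
  draws <- if (inherits(psa, "iris_psa")) psa$draws else psa
  prob <- vapply(wtp_grid, function(l)
    mean(l * draws$inc_qaly - draws$inc_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Empirical 95% percentile interval
#'
#' Returns the 2.5th and 97.5th empirical percentiles under the
#' linear-interpolation convention (R's default quantile type 7); for
#' samples `1:1000` this gives (25.975, 975.025).
#'
#' @param samples Numeric vector with at least two values.
#' @param level Interval level (default 0.95).
#' @return Named vector `c(low, high)`.
#' @export
percentile_interval <- function(samples, level = 0.95) {
  if (length(samples) < 2) stop("need at least two samples")
  a <- (1 - level) / 2
  q <- stats::quantile(samples, c(a, 1 - a), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}
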
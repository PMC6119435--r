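#' Pooled national parameter set for the IRIS cost-utility model
#'
#' Returns the complete base-case parameter set for the pooled national
#' analysis of the IRIS programme: per-arm transition probabilities over the
#' five health states, the starting distribution, state utilities, costs,
#' run settings and a 95% uncertainty specification for every parameter that
#' has one. Stay probabilities are never stored; they are always recomputed
#' as the complement of the exit probabilities when a transition matrix is
#' built (see [build_transition_matrix()]).
#'
#' Monetary values are GBP at 2015/16 prices. The per-cycle intervention
#' cost of GBP 0.46 per registered woman is the 6-month programme budget
#' across the pooled sites (GBP 272,613) divided by the number of registered
#' women aged 16+ in the trained practices (595,902). The one-time referral
#' cost of GBP 312 is charged per entrant to the seeing-advocate state. The
#' GBP 2043 six-month cost of abuse applies to all abused states, scaled by
#' the two identified-state cost weights.
#'
#' @return An object of class `iris_parameters`.
#' @export
#' @examples
#' p <- default_iris_parameters()
#' p$prevalence
#' validate_parameters(p)
default_iris_parameters <- function() {
  p <- structure(list(
    prevalence = 0.17,
    # split of the abused mass at model start over {U, A, I}; U is the
    # complement of the two identified fractions and is stored for clarity
    start_split_abused = c(U = 0.964, A = 0.003, I = 0.033),
    transitions = list(
      control = list(
        N = c(U = 0.0037, D = 0.00551),
        U = c(N = 0.0500, A = 0.0005, I = 0.0027, D = 0.00554),
        A = c(N = 0.1408, D = 0.00554),
        I = c(N = 0.0781, D = 0.00554)),
      intervention = list(
        N = c(U = 0.0037, D = 0.00551),
        U = c(N = 0.0500, A = 0.0056, I = 0.0109, D = 0.00554),
        A = c(N = 0.1408, D = 0.00554),
        I = c(N = 0.0781, D = 0.00554))),
    utilities = c(N = 0.85, U = 0.63, A = 0.65, I = 0.63, D = 0),
    costs = list(
      abuse_per_cycle = 2043,
      weight_seeing = 1,
      weight_not_seeing = 1,
      intervention_per_woman_cycle = 0.46,
      referral_once = 312,
      # fraction of the six-month abuse cost borne by the NHS; not an
      # observed quantity -- back-derived once from the published
      # NHS-perspective control-arm total with derive_nhs_cost_share()
      # and frozen here. Override in config for other health systems.
      nhs_cost_share = 0.2860
    ),
    settings = list(
      discount_rate_annual = 0.035,
      cycle_length_years = 0.5,
      n_cycles = 20L,
      wtp = 20000,
      cohort_size = 10000,
      n_psa = 1000L,
      rng_seed = 1234L
    ),
    options = list(
      stay_mode = "complement",
      charge_initial_advocates = FALSE,
      dirichlet_mode = "element_beta"
    ),
    uncertainty = default_uncertainty()
  ), class = "iris_parameters")
  p
}

# The 95% uncertainty interval and distribution family for every parameter
# that carries one, keyed by parameter id (see param_ids()).
default_uncertainty <- function() {
  u <- list(
    prevalence            = dist_spec("beta", 0.17, 0.147, 0.194),
    start_seeing          = dist_spec("uniform", 0.003, 0, 0.0066),
    start_not_seeing      = dist_spec("uniform", 0.033, 0, 0.0660),
    tp_N_U                = dist_spec("dirichlet_row_member", 0.0037, 0.0004, 0.0106),
    tp_N_D                = dist_spec("dirichlet_row_member", 0.00551, 0.0010, 0.0136),
    tp_control_U_N        = dist_spec("dirichlet_row_member", 0.0500, 0.0450, 0.0553),
    tp_control_U_I        = dist_spec("dirichlet_row_member", 0.0027, 0.0016, 0.0040),
    tp_control_U_A        = dist_spec("dirichlet_row_member", 0.0005, 0.0001, 0.0011),
    tp_control_U_D        = dist_spec("dirichlet_row_member", 0.00554, 0.0039, 0.0074),
    tp_intervention_U_N   = dist_spec("dirichlet_row_member", 0.0500, 0.0450, 0.0553),
    tp_intervention_U_I   = dist_spec("dirichlet_row_member", 0.0109, 0.0086, 0.0135),
    tp_intervention_U_A   = dist_spec("dirichlet_row_member", 0.0056, 0.0040, 0.0076),
    tp_intervention_U_D   = dist_spec("dirichlet_row_member", 0.00554, 0.0039, 0.0074),
    tp_A_N                = dist_spec("dirichlet_row_member", 0.1408, 0.0707, 0.2301),
    tp_A_D                = dist_spec("dirichlet_row_member", 0.00554, 0.0000, 0.0309),
    tp_I_N                = dist_spec("dirichlet_row_member", 0.0781, 0.0136, 0.1912),
    tp_I_D                = dist_spec("dirichlet_row_member", 0.00554, 0.0000, 0.0438),
    util_N                = dist_spec("beta", 0.85, 0.840, 0.860),
    util_U                = dist_spec("beta", 0.63, 0.503, 0.749),
    util_A                = dist_spec("beta", 0.65, 0.518, 0.771),
    util_I                = dist_spec("beta", 0.63, 0.503, 0.749),
    cost_intervention     = dist_spec("gamma", 0.46, 0.01, 1.69),
    cost_referral         = dist_spec("gamma", 312, 8, 1127),
    cost_abuse            = dist_spec("gamma", 2043, 52, 7536),
    cost_weight_seeing    = dist_spec("gamma", 1, 0.75, 1.25),
    cost_weight_not_seeing = dist_spec("gamma", 1, 0.9, 1.1)
  )
  u
}

# data source labels for the audit export, by parameter id
param_sources <- function() {
  c(prevalence = "cross-sectional general-practice survey",
    start_seeing = "model calibration", start_not_seeing = "model calibration",
    tp_N_U = "model calibration", tp_N_D = "national mortality statistics",
    tp_control_U_N = "model calibration",
    tp_control_U_I = "programme monitoring data",
    tp_control_U_A = "programme monitoring data",
    tp_control_U_D = "advocacy systematic review",
    tp_intervention_U_N = "model calibration",
    tp_intervention_U_I = "programme monitoring data",
    tp_intervention_U_A = "programme monitoring data",
    tp_intervention_U_D = "advocacy systematic review",
    tp_A_N = "advocacy systematic review", tp_A_D = "advocacy systematic review",
    tp_I_N = "advocacy systematic review", tp_I_D = "advocacy systematic review",
    util_N = "population utility norms", util_U = "abuse health-state valuation",
    util_A = "abuse health-state valuation", util_I = "abuse health-state valuation",
    cost_intervention = "programme budgets", cost_referral = "programme budgets",
    cost_abuse = "national cost-of-abuse report",
    cost_weight_seeing = "assumption", cost_weight_not_seeing = "assumption")
}

# Printed stay probabilities, used only under stay_mode = "printed_renormalized".
# The published table rounds most rows to the exit complement, but the two
# U rows differ materially from their complements; this mode exists to
# explore that discrepancy and is not the base case.
printed_stay <- function(arm) {
  list(N = 0.9908,
       U = if (arm == "control") 0.9444 else 0.9419,
       A = 0.8536,
       I = 0.9163)
}

#' Parameter ids recognised by the sensitivity machinery
#'
#' Every entry of the uncertainty block is keyed by one of these ids.
#' Transition ids follow the pattern `tp_<from>_<to>` for rows shared by
#' both arms and `tp_<arm>_U_<to>` for the arm-specific row out of the
#' abused-unidentified state.
#'
#' @param params An `iris_parameters` object.
#' @return Character vector of ids.
#' @export
param_ids <- function(params = default_iris_parameters()) {
  names(params$uncertainty)
}

#' Read a single parameter value by id
#'
#' @param params An `iris_parameters` object.
#' @param id A parameter id (see [param_ids()]).
#' @return The current scalar value of that parameter.
#' @export
param_value <- function(params, id) {
  tp <- parse_tp_id(id)
  if (!is.null(tp)) {
    arm <- tp$arm %||% "control"
    return(unname(params$transitions[[arm]][[tp$from]][tp$to]))
  }
  switch(id,
    prevalence = params$prevalence,
    start_seeing = unname(params$start_split_abused["A"]),
    start_not_seeing = unname(params$start_split_abused["I"]),
    util_N = unname(params$utilities["N"]),
    util_U = unname(params$utilities["U"]),
    util_A = unname(params$utilities["A"]),
    util_I = unname(params$utilities["I"]),
    cost_intervention = params$costs$intervention_per_woman_cycle,
    cost_referral = params$costs$referral_once,
    cost_abuse = params$costs$abuse_per_cycle,
    cost_weight_seeing = params$costs$weight_seeing,
    cost_weight_not_seeing = params$costs$weight_not_seeing,
    nhs_cost_share = params$costs$nhs_cost_share,
    stop("unknown parameter id: ", id))
}

#' Set a single parameter value by id
#'
#' Setting one of the starting-split fractions recomputes the
#' abused-unidentified share as the complement. Setting a transition
#' probability updates the stored exit; the stay probability is derived
#' later, when the matrix is built.
#'
#' @inheritParams param_value
#' @param value New value.
#' @return The modified `iris_parameters` object.
#' @export
set_param_value <- function(params, id, value) {
  tp <- parse_tp_id(id)
  if (!is.null(tp)) {
    arms <- if (is.null(tp$arm)) c("control", "intervention") else tp$arm
    for (a in arms) params$transitions[[a]][[tp$from]][tp$to] <- value
    return(params)
  }
  switch(id,
    prevalence = { params$prevalence <- value },
    start_seeing = {
      params$start_split_abused["A"] <- value
      params$start_split_abused["U"] <-
        1 - value - params$start_split_abused[["I"]]
    },
    start_not_seeing = {
      params$start_split_abused["I"] <- value
      params$start_split_abused["U"] <-
        1 - params$start_split_abused[["A"]] - value
    },
    util_N = { params$utilities["N"] <- value },
    util_U = { params$utilities["U"] <- value },
    util_A = { params$utilities["A"] <- value },
    util_I = { params$utilities["I"] <- value },
    cost_intervention = { params$costs$intervention_per_woman_cycle <- value },
    cost_referral = { params$costs$referral_once <- value },
    cost_abuse = { params$costs$abuse_per_cycle <- value },
    cost_weight_seeing = { params$costs$weight_seeing <- value },
    cost_weight_not_seeing = { params$costs$weight_not_seeing <- value },
    nhs_cost_share = { params$costs$nhs_cost_share <- value },
    stop("unknown parameter id: ", id))
  params
}

# parse "tp_N_U", "tp_control_U_A" etc.; NULL if not a transition id
parse_tp_id <- function(id) {
  if (!startsWith(id, "tp_")) return(NULL)
  parts <- strsplit(id, "_", fixed = TRUE)[[1]][-1]
  if (length(parts) == 2) {
    list(arm = NULL, from = parts[1], to = parts[2])
  } else if (length(parts) == 3 && parts[1] %in% c("control", "intervention")) {
    list(arm = parts[1], from = parts[2], to = parts[3])
  } else {
    stop("malformed transition id: ", id)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs: probabilities and
#' utilities in [0, 1], non-negative costs, the starting split summing to 1,
#' every transition row's exit probabilities summing to strictly less than 1
#' (so the stay complement is positive), coherent uncertainty limits, and
#' valid run settings.
#'
#' @param params An `iris_parameters` object.
#' @return Character vector of human-readable violations; empty when the
#'   set is valid.
#' @export
#' @examples
#' validate_parameters(default_iris_parameters())
validate_parameters <- function(params) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)

  chk(is.numeric(params$prevalence) &&
        params$prevalence >= 0 && params$prevalence <= 1,
      "prevalence: must be a probability in [0, 1]")

  ss <- params$start_split_abused
  chk(all(c("U", "A", "I") %in% names(ss)),
      "start_split_abused: must name U, A and I")
  if (all(c("U", "A", "I") %in% names(ss))) {
    chk(all(ss >= 0 & ss <= 1), "start_split_abused: fractions must lie in [0, 1]")
    chk(abs(sum(ss[c("U", "A", "I")]) - 1) <= 1e-9,
        "start_split_abused: fractions must sum to 1 within 1e-9")
  }

  ex <- allowed_exits()
  for (arm in c("control", "intervention")) {
    tr <- params$transitions[[arm]]
    for (from in names(ex)) {
      row <- tr[[from]]
      chk(!is.null(row) && all(ex[[from]] %in% names(row)),
          sprintf("transitions$%s$%s: missing exit probabilities", arm, from))
      if (is.null(row)) next
      chk(all(row >= 0 & row <= 1),
          sprintf("transitions$%s$%s: probabilities must lie in [0, 1]", arm, from))
      chk(sum(row) < 1,
          sprintf(
            "transitions$%s$%s: exit probabilities sum to %.5f; must be < 1 so the stay complement is positive",
            arm, from, sum(row)))
      extra <- setdiff(names(row), ex[[from]])
      chk(length(extra) == 0,
          sprintf("transitions$%s$%s: disallowed transitions to %s",
                  arm, from, paste(extra, collapse = ", ")))
    }
  }

  u <- params$utilities
  chk(all(iris_states() %in% names(u)), "utilities: must name all five states")
  chk(all(u >= 0 & u <= 1), "utilities: must lie in [0, 1]")
  if ("D" %in% names(u)) chk(u[["D"]] == 0, "utilities: dead state must have utility 0")

  for (cn in c("abuse_per_cycle", "weight_seeing", "weight_not_seeing",
               "intervention_per_woman_cycle", "referral_once")) {
    chk(is.numeric(params$costs[[cn]]) && params$costs[[cn]] >= 0,
        sprintf("costs$%s: must be non-negative", cn))
  }
  chk(params$costs$nhs_cost_share >= 0 && params$costs$nhs_cost_share <= 1,
      "costs$nhs_cost_share: must be a fraction in [0, 1]")

  s <- params$settings
  chk(s$discount_rate_annual >= 0, "settings$discount_rate_annual: must be >= 0")
  chk(s$cycle_length_years > 0, "settings$cycle_length_years: must be > 0")
  chk(is.numeric(s$n_cycles) && s$n_cycles >= 1,
      "settings$n_cycles: must be a positive count")
  chk(s$wtp >= 0, "settings$wtp: must be >= 0")

  for (id in names(params$uncertainty)) {
    bad <- validate_dist_spec(params$uncertainty[[id]])
    if (length(bad)) v <- c(v, sprintf("uncertainty$%s: %s", id, bad))
  }

  chk(params$options$stay_mode %in% c("complement", "printed_renormalized"),
      "options$stay_mode: must be 'complement' or 'printed_renormalized'")
  chk(params$options$dirichlet_mode %in% c("element_beta", "dirichlet"),
      "options$dirichlet_mode: must be 'element_beta' or 'dirichlet'")

  v
}

#' @export
print.iris_parameters <- function(x, ...) {
  cat("IRIS cost-utility model parameters\n")
  cat(sprintf("  prevalence of abuse at start: %.3f\n", x$prevalence))
  cat(sprintf("  horizon: %d cycles of %.1f years, discount %.1f%%/year\n",
              x$settings$n_cycles, x$settings$cycle_length_years,
              100 * x$settings$discount_rate_annual))
  cat(sprintf("  WTP threshold: GBP %s per QALY\n",
              format(x$settings$wtp, big.mark = ",")))
  cat(sprintf("  %d parameters with uncertainty specifications\n",
              length(x$uncertainty)))
  nv <- length(validate_parameters(x))
  cat(if (nv == 0) "  valid\n" else sprintf("  INVALID: %d violations\n", nv))
  invisible(x)
}

#' Write a parameter set to a plain-text (YAML) file
#'
#' The file is a flat, human-readable document with nested sections for the
#' two arms; [load_parameters()] reads it back to an identical object.
#'
#' @param params An `iris_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  doc <- list(
    prevalence = params$prevalence,
    start_split_abused = as.list(params$start_split_abused),
    transitions = lapply(params$transitions, function(arm)
      lapply(arm, as.list)),
    utilities = as.list(params$utilities),
    costs = params$costs,
    settings = params$settings,
    options = params$options,
    uncertainty = lapply(params$uncertainty, function(sp)
      list(family = sp$family, base = sp$base, low = sp$low, high = sp$high))
  )
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Read a parameter set from a plain-text (YAML) file
#'
#' Unspecified optional fields fall back to the pooled national defaults;
#' the four required sections are `prevalence`, `start_split_abused`,
#' `transitions` and `utilities`. The returned object is validated and the
#' function fails with the list of violations if any invariant is broken.
#'
#' @param path Path to a file written by [write_parameters()] (or edited by
#'   hand following the same schema).
#' @return An `iris_parameters` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  doc <- yaml::read_yaml(path)
  defaults <- default_iris_parameters()

  for (field in c("prevalence", "start_split_abused", "transitions", "utilities"))
    if (is.null(doc[[field]]))
      stop("parameter file is missing required field '", field, "'")

  p <- defaults
  p$prevalence <- doc$prevalence
  p$start_split_abused <- unlist(doc$start_split_abused)[c("U", "A", "I")]
  p$transitions <- lapply(doc$transitions, function(arm) lapply(arm, unlist))
  p$utilities <- unlist(doc$utilities)[iris_states()]
  for (blk in c("costs", "settings", "options"))
    if (!is.null(doc[[blk]]))
      p[[blk]] <- utils::modifyList(defaults[[blk]], doc[[blk]])
  p$settings$n_cycles <- as.integer(p$settings$n_cycles)
  p$settings$n_psa <- as.integer(p$settings$n_psa)
  p$settings$rng_seed <- as.integer(p$settings$rng_seed)
  if (!is.null(doc$uncertainty)) {
    p$uncertainty <- lapply(doc$uncertainty, function(sp)
      dist_spec(sp$family, sp$base, sp$low, sp$high))
  }

  bad <- validate_parameters(p)
  if (length(bad))
    stop("invalid parameter file '", path, "':\n  ",
         paste(bad, collapse = "\n  "))
  p
}

#' Export the uncertainty table as a machine-readable CSV
#'
#' One row per parameter: id, base value, lower and upper 95% limits,
#' distribution family and data source. Intended as an audit trail of the
#' model inputs.
#'
#' @param params An `iris_parameters` object.
#' @param path Optional output path; when `NULL` the data frame is returned
#'   without writing.
#' @return A data frame (invisibly when `path` is given).
#' @export
export_parameter_table <- function(params, path = NULL) {
  src <- param_sources()
  ids <- names(params$uncertainty)
  tab <- data.frame(
    parameter = ids,
    base = vapply(params$uncertainty, function(s) s$base, numeric(1)),
    low = vapply(params$uncertainty, function(s) s$low, numeric(1)),
    high = vapply(params$uncertainty, function(s) s$high, numeric(1)),
    family = vapply(params$uncertainty, function(s) s$family, character(1)),
    source = unname(ifelse(ids %in% names(src), src[ids], "")),
    row.names = NULL)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
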
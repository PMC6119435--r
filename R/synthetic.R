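#' Specification for a random synthetic parameter set
#'
#' Controls the generator used by the property-based tests: every pipeline
#' stage can be exercised on structurally valid random inputs without any
#' external data. Generated sets keep the model's structural sparsity (the
#' allowed-exit pattern of the five states); see [random_dense_matrix()] for
#' the unstructured engine stress-test variant.
#'
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @param cost_scale Scale of the per-cycle abuse cost (GBP).
#' @param utility_range Interval within [0, 1] for living-state utilities.
#' @param exit_cap Upper bound (< 1) on the sum of exit probabilities per
#'   row; `0` produces pure-stay (identity) dynamics.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, cost_scale = 2000,
                           utility_range = c(0.4, 0.9),
                           exit_cap = 0.3) {
  stopifnot(exit_cap >= 0, exit_cap < 1,
            utility_range[1] >= 0, utility_range[2] <= 1,
            utility_range[1] <= utility_range[2],
            cost_scale >= 0)
  structure(list(seed = as.integer(seed), n_living_states = 4L,
                 cost_scale = cost_scale, utility_range = utility_range,
                 exit_cap = exit_cap),
            class = "synthetic_spec")
}

#' Random dense row-stochastic matrix with an absorbing last state
#'
#' Engine stress-test companion to [random_parameter_set()]: ignores the
#' model's structural sparsity and allows every living-to-living move.
#'
#' @param seed Integer seed.
#' @param k Number of states including the absorbing one (default 5).
#' @return A k x k row-stochastic matrix whose last state is absorbing.
#' @export
random_dense_matrix <- function(seed = 1L, k = 5L) {
  set.seed(seed)
  st <- c(paste0("S", seq_len(k - 1)), "D")
  M <- matrix(0, k, k, dimnames = list(st, st))
  for (i in seq_len(k - 1)) {
    x <- stats::runif(k)
    x[i] <- x[i] + k  # keep rows stay-dominated, like health-state models
    M[i, ] <- x / sum(x)
  }
  M[k, k] <- 1
  M
}

#' Generate a random, structurally valid parameter set
#'
#' Draws exit probabilities per transition row (summing below the cap),
#' utilities within the configured range, non-negative costs, and a
#' coherent uncertainty specification (low <= base <= high, family-specific
#' bounds respected) for every parameter. The result always passes
#' [validate_parameters()].
#'
#' @param spec A [synthetic_spec()].
#' @return An `iris_parameters` object.
#' @export
#' @examples
#' p <- random_parameter_set(synthetic_spec(seed = 7))
#' length(validate_parameters(p))  # 0
random_parameter_set <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  ex <- allowed_exits()

  draw_row <- function(targets) {
    if (spec$exit_cap == 0)
      return(stats::setNames(rep(0, length(targets)), targets))
    raw <- stats::runif(length(targets))
    tot <- stats::runif(1, 0, spec$exit_cap)
    stats::setNames(raw / sum(raw) * tot, targets)
  }
  draw_arm <- function() lapply(ex, draw_row)

  prevalence <- stats::runif(1, 0.05, 0.4)
  sA <- stats::runif(1, 0, 0.05)
  sI <- stats::runif(1, 0, 0.1)
  ur <- spec$utility_range
  utils_liv <- stats::runif(4, ur[1], ur[2])

  p <- default_iris_parameters()
  p$prevalence <- prevalence
  p$start_split_abused <- c(U = 1 - sA - sI, A = sA, I = sI)
  p$transitions <- list(control = draw_arm(), intervention = draw_arm())
  p$utilities <- c(stats::setNames(utils_liv, living_states()), D = 0)
  p$costs$abuse_per_cycle <- stats::runif(1, 0.1, 2) * spec$cost_scale
  p$costs$weight_seeing <- stats::runif(1, 0.7, 1.3)
  p$costs$weight_not_seeing <- stats::runif(1, 0.7, 1.3)
  p$costs$intervention_per_woman_cycle <- stats::runif(1, 0, 2)
  p$costs$referral_once <- stats::runif(1, 0, 500)

  # coherent uncertainty specs around the drawn bases
  p$uncertainty <- synthetic_uncertainty(p)
  stopifnot(length(validate_parameters(p)) == 0)
  p
}

synthetic_uncertainty <- function(p) {
  families <- vapply(default_uncertainty(), function(s) s$family, character(1))
  out <- list()
  for (id in names(families)) {
    base <- tryCatch(param_value(p, id), error = function(e) NULL)
    if (is.null(base)) next
    fam <- families[[id]]
    if (base == 0) {
      out[[id]] <- dist_spec("fixed", 0)
      next
    }
    lo <- base * stats::runif(1, 0.5, 0.95)
    hi <- base * stats::runif(1, 1.05, 1.5)
    if (fam %in% c("beta", "dirichlet_row_member", "uniform")) {
      hi <- min(hi, 1)
      if (hi < base) hi <- base
    }
    out[[id]] <- dist_spec(fam, base, lo, hi)
  }
  out
}

#' Miniature closed-form model fixtures
#'
#' A named collection of tiny chains and degenerate parameter sets whose
#' traces and results are known analytically; they anchor the unit tests of
#' every module.
#'
#' \describe{
#'   \item{two_state_death}{alive/dead chain with per-cycle death 0.1;
#'     dead fraction after two cycles is 1 - 0.9^2 = 0.19.}
#'   \item{symmetric_switch}{two living states swapping with equal
#'     probability and equal death rates; conditional-on-alive long-run
#'     distribution is (0.5, 0.5).}
#'   \item{detailed_balance}{two living states, forward 0.1, back 0.3, no
#'     death; stationary distribution (0.75, 0.25).}
#'   \item{zero_cost}{the default parameter set with every cost zero.}
#'   \item{equal_arms}{the default parameter set with the intervention arm's
#'     transitions set equal to the control arm's and the programme cost
#'     zero, so the two arms are identical.}
#' }
#'
#' @return Named list; chain entries hold `matrix`, `start`, `dead` and an
#'   `expected` list, parameter entries hold `params` and `expected`.
#' @export
toy_models <- function() {
  two_state <- matrix(c(0.9, 0.1,
                        0,   1), 2, 2, byrow = TRUE,
                      dimnames = list(c("alive", "dead"), c("alive", "dead")))
  sym <- matrix(c(0.75, 0.20, 0.05,
                  0.20, 0.75, 0.05,
                  0,    0,    1), 3, 3, byrow = TRUE,
                dimnames = list(c("X", "Y", "D"), c("X", "Y", "D")))
  det <- matrix(c(0.9, 0.1,
                  0.3, 0.7), 2, 2, byrow = TRUE,
                dimnames = list(c("N", "U"), c("N", "U")))

  zero_cost <- default_iris_parameters()
  zero_cost$costs$abuse_per_cycle <- 0
  zero_cost$costs$intervention_per_woman_cycle <- 0
  zero_cost$costs$referral_once <- 0

  equal_arms <- default_iris_parameters()
  equal_arms$transitions$intervention <- equal_arms$transitions$control
  equal_arms$costs$intervention_per_woman_cycle <- 0

  list(
    two_state_death = list(
      matrix = two_state, start = c(alive = 1, dead = 0), dead = "dead",
      expected = list(dead_after_2 = 0.19)),
    symmetric_switch = list(
      matrix = sym, start = c(X = 1, Y = 0, D = 0), dead = "D",
      expected = list(qsd = c(X = 0.5, Y = 0.5))),
    detailed_balance = list(
      matrix = det, start = c(N = 0.5, U = 0.5), dead = NULL,
      expected = list(qsd = c(N = 0.75, U = 0.25))),
    zero_cost = list(
      params = zero_cost,
      expected = list(cost = 0)),
    equal_arms = list(
      params = equal_arms,
      expected = list(incremental_cost = 0, incremental_qaly = 0, nmb = 0))
  )
}
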
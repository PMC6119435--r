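#' Build the per-cycle transition matrix for one arm
#'
#' Rows are assembled from the arm's exit probabilities; the probability of
#' staying in a state is the complement of its exits, so every row sums to
#' one by construction. Structural zeros are enforced: women in the
#' not-abused state cannot move directly to an identified state, and women
#' in an identified state can only stay, recover to not-abused, or die.
#'
#' Under `options$stay_mode = "printed_renormalized"` the historically
#' published stay values are inserted instead and each row is renormalised
#' to sum to one. This mode exists only to explore the published rounding
#' discrepancy in the abused-unidentified rows; the complement construction
#' is the base case.
#'
#' @param params An `iris_parameters` object.
#' @param arm `"control"` or `"intervention"`.
#' @return A 5x5 row-stochastic matrix in state order N, U, A, I, D with
#'   attribute `arm`.
#' @export
#' @examples
#' m <- build_transition_matrix(default_iris_parameters(), "control")
#' rowSums(m)
build_transition_matrix <- function(params, arm = c("control", "intervention")) {
  arm <- match.arg(arm)
  st <- iris_states()
  M <- matrix(0, 5, 5, dimnames = list(st, st))
  tr <- params$transitions[[arm]]
  for (from in living_states()) {
    row <- tr[[from]]
    if (sum(row) >= 1)
      stop(sprintf(
        "%s arm, row %s: exit probabilities sum to %.5f >= 1; no stay probability remains",
        arm, from, sum(row)))
    M[from, names(row)] <- row
    M[from, from] <- 1 - sum(row)
  }
  M["D", "D"] <- 1
  if (identical(params$options$stay_mode, "printed_renormalized")) {
    ps <- printed_stay(arm)
    for (from in living_states()) {
      M[from, from] <- ps[[from]]
      M[from, ] <- M[from, ] / sum(M[from, ])
    }
  }
  structure(M, arm = arm)
}

#' Starting state occupancy of the cohort
#'
#' The not-abused state receives one minus the prevalence of abuse; the
#' abused mass is split over the three abused states by the starting split;
#' nobody starts dead.
#'
#' @param params An `iris_parameters` object.
#' @return Named numeric vector over the five states, summing to 1.
#' @export
#' @examples
#' initial_distribution(default_iris_parameters())
initial_distribution <- function(params) {
  ss <- params$start_split_abused
  out <- c(N = 1 - params$prevalence,
           U = params$prevalence * ss[["U"]],
           A = params$prevalence * ss[["A"]],
           I = params$prevalence * ss[["I"]],
           D = 0)
  out
}

#' Run the deterministic cohort trace
#'
#' Iterates the cohort distribution through the transition matrix for
#' `n_cycles` cycles, recording state occupancy at every time point
#' (0 ... n_cycles) and, for each cycle, the fraction of the cohort newly
#' entering each state (transitions from any *other* state landing at the
#' end of that cycle; women already in a state at time 0 are not entrants).
#'
#' Works for any square row-stochastic matrix, which the toy fixtures in
#' [toy_models()] rely on.
#'
#' @param matrix Square row-stochastic matrix with identical row/column names.
#' @param start Named occupancy vector summing to 1.
#' @param n_cycles Number of cycles (>= 1).
#' @return An object of class `iris_trace`: a list with `occupancy`
#'   ((n_cycles + 1) x k matrix, rows indexed by time point) and `entrants`
#'   (n_cycles x k matrix, rows indexed by cycle).
#' @export
#' @examples
#' p <- default_iris_parameters()
#' tr <- run_cohort(build_transition_matrix(p, "control"),
#'                  initial_distribution(p), 20)
#' head(tr$occupancy)
run_cohort <- function(matrix, start, n_cycles) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  k <- ncol(matrix)
  st <- colnames(matrix)
  start <- start[st]
  occ <- base::matrix(0, n_cycles + 1, k, dimnames = list(0:n_cycles, st))
  ent <- base::matrix(0, n_cycles, k, dimnames = list(1:n_cycles, st))
  occ[1, ] <- start
  off <- matrix; diag(off) <- 0  # flows from other states only
  for (cyc in seq_len(n_cycles)) {
    prev <- occ[cyc, ]
    occ[cyc + 1, ] <- prev %*% matrix
    ent[cyc, ] <- prev %*% off
  }
  structure(list(occupancy = occ, entrants = ent), class = "iris_trace")
}

#' @export
print.iris_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1
  cat(sprintf("<iris_trace: %d cycles, %d states>\n", n, ncol(x$occupancy)))
  print(utils::head(round(x$occupancy, 5)))
  invisible(x)
}

#' Long-run state distribution conditional on being alive
#'
#' Iterates the chain while renormalising the mass over the living states
#' after every cycle, until the distribution changes by less than `tol` or
#' `max_cycles` is reached. With an absorbing death state the unconditioned
#' chain converges to everyone dead; the quantity of interest for
#' calibration is the limiting distribution among survivors, which this
#' computes.
#'
#' @param matrix Square row-stochastic matrix; the absorbing death state is
#'   identified by `dead` (set `dead = NULL` for chains without death).
#' @param max_cycles Iteration cap (default 3000, the model's long-run
#'   convention).
#' @param tol Convergence tolerance on the max absolute change per cycle.
#' @param dead Name of the absorbing state, or `NULL`.
#' @param start Optional starting distribution over all states; defaults to
#'   uniform over the living states.
#' @return Named vector over the living states summing to 1, with
#'   attributes `converged` (logical) and `iterations`.
#' @export
#' @examples
#' m <- build_transition_matrix(default_iris_parameters(), "control")
#' quasi_stationary_distribution(m)
quasi_stationary_distribution <- function(matrix, max_cycles = 3000,
                                          tol = 1e-12, dead = "D",
                                          start = NULL) {
  if (max_cycles < 1) stop("max_cycles must be >= 1")
  st <- colnames(matrix)
  living <- if (is.null(dead)) st else setdiff(st, dead)
  sub <- matrix[living, living, drop = FALSE]
  v <- if (is.null(start)) {
    stats::setNames(rep(1 / length(living), length(living)), living)
  } else {
    x <- start[living]; x / sum(x)
  }
  converged <- FALSE
  iters <- 0L
  for (i in seq_len(max_cycles)) {
    nxt <- as.vector(v %*% sub)
    nxt <- nxt / sum(nxt)
    iters <- i
    if (max(abs(nxt - v)) < tol) {
      v <- stats::setNames(nxt, living)
      converged <- TRUE
      break
    }
    v <- stats::setNames(nxt, living)
  }
  structure(v, converged = converged, iterations = iters)
}

#' Export a cohort trace as a long-format data frame
#'
#' @param trace An `iris_trace`.
#' @return Data frame with columns `time_point`, `state`, `occupancy`,
#'   `entrants` (entrants are `NA` at time 0, which is a stock, not a flow).
#' @export
trace_to_df <- function(trace) {
  occ <- trace$occupancy
  ent <- trace$entrants
  n <- nrow(occ) - 1
  st <- colnames(occ)
  data.frame(
    time_point = rep(0:n, times = length(st)),
    state = rep(st, each = n + 1),
    occupancy = as.vector(occ),
    entrants = as.vector(rbind(NA_real_, ent)),
    row.names = NULL)
}
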
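# Independent oracles used across the test files.

# start . M^t via repeated squaring -- an independent route to the trace
matrix_power <- function(M, t) {
  k <- ncol(M)
  out <- diag(k); dimnames(out) <- dimnames(M)
  base <- M
  while (t > 0) {
    if (t %% 2 == 1) out <- out %*% base
    base <- base %*% base
    t <- t %/% 2
  }
  out
}

# seeded per-individual microsimulation of a cohort; returns occupancy
# fractions at time points 0..n_cycles
microsimulate <- function(M, start, n_cycles, n_ind = 10000, seed = 42) {
  set.seed(seed)
  k <- ncol(M)
  st <- colnames(M)
  # deterministic initial allocation (largest remainder) so that only the
  # transition sampling is stochastic
  exact <- start[st] * n_ind
  cnt <- floor(exact)
  rem <- n_ind - sum(cnt)
  if (rem > 0) {
    extra <- order(exact - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  state <- rep(seq_len(k), times = cnt)
  occ <- matrix(0, n_cycles + 1, k, dimnames = list(0:n_cycles, st))
  occ[1, ] <- tabulate(state, k) / n_ind
  for (cyc in seq_len(n_cycles)) {
    for (s in seq_len(k)) {
      idx <- which(state == s)
      if (length(idx))
        state[idx] <- sample.int(k, length(idx), replace = TRUE, prob = M[s, ])
    }
    occ[cyc + 1, ] <- tabulate(state, k) / n_ind
  }
  occ
}

# quantile of a beta density by numeric quadrature + root finding,
# independent of stats::qbeta
quadrature_beta_quantile <- function(p, shape1, shape2) {
  cdf <- function(x)
    stats::integrate(function(u) stats::dbeta(u, shape1, shape2),
                     0, x, rel.tol = 1e-10)$value
  stats::uniroot(function(x) cdf(x) - p, c(1e-12, 1 - 1e-12),
                 tol = 1e-10)$root
}

# a parameter set with frozen identity dynamics: nobody moves or dies
frozen_params <- function(discount = 0) {
  p <- random_parameter_set(synthetic_spec(seed = 1, exit_cap = 0))
  p$settings$discount_rate_annual <- discount
  p
}
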
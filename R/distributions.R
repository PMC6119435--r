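#' Uncertainty specification for a single model parameter
#'
#' Each uncertain parameter carries a distribution family, its base-case
#' value and the lower/upper limits of its 95% uncertainty interval. The
#' family is one of `beta` (probabilities and utilities), `gamma` (costs and
#' cost weights), `dirichlet_row_member` (a member of a transition row, whose
#' stay probability is always re-derived as the complement), `uniform`
#' (starting-split fractions) or `fixed` (no uncertainty).
#'
#' @param family One of `"beta"`, `"gamma"`, `"dirichlet_row_member"`,
#'   `"uniform"`, `"fixed"`.
#' @param base Base-case value (treated as the distribution mean when
#'   fitting, except for `uniform` where the bounds are used directly).
#' @param low,high Lower and upper 95% limits; for `fixed` both must equal
#'   `base`.
#' @return An object of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("beta", 0.17, 0.147, 0.194)
dist_spec <- function(family, base, low = base, high = base) {
  family <- match.arg(family,
                      c("beta", "gamma", "dirichlet_row_member", "uniform", "fixed"))
  spec <- structure(list(family = family, base = base, low = low, high = high),
                    class = "dist_spec")
  bad <- validate_dist_spec(spec)
  if (length(bad)) stop("invalid distribution spec: ", paste(bad, collapse = "; "))
  spec
}

validate_dist_spec <- function(spec) {
  out <- character()
  if (!is.numeric(spec$base) || !is.numeric(spec$low) || !is.numeric(spec$high))
    return("base/low/high must be numeric")
  if (!(spec$low <= spec$base && spec$base <= spec$high))
    out <- c(out, sprintf("limits must satisfy low <= base <= high (got %g, %g, %g)",
                          spec$low, spec$base, spec$high))
  if (spec$family == "fixed" && !(spec$low == spec$base && spec$high == spec$base))
    out <- c(out, "fixed family requires low = base = high")
  if (spec$family %in% c("beta", "dirichlet_row_member") &&
      (spec$low < 0 || spec$high > 1))
    out <- c(out, "beta-type limits must lie in [0, 1]")
  if (spec$family == "gamma" && spec$low < 0)
    out <- c(out, "gamma limits must be non-negative")
  out
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec %s: base %g [%g, %g]>\n", x$family, x$base, x$low, x$high))
  invisible(x)
}

is_degenerate_spec <- function(spec) {
  spec$family == "fixed" || (spec$low == spec$high)
}

#' Fit a sampling distribution to an uncertainty specification
#'
#' Method-of-moments fit treating `base` as the mean and
#' `(high - low) / 3.92` as the standard deviation (the width of a 95%
#' normal interval). Beta distributions get shape parameters from the
#' mean/sd pair; gamma distributions get shape and scale; uniform uses the
#' bounds directly; fixed is a point mass. `dirichlet_row_member` is fitted
#' as an independent per-element beta; the row is re-closed through the stay
#' complement after sampling (see [sample_parameter_set()]).
#'
#' @param spec A [dist_spec()].
#' @param id Optional parameter name used in error messages.
#' @return A list with the family and its fitted parameters, of class
#'   `fitted_dist`.
#' @export
#' @examples
#' fit_distribution(dist_spec("beta", 0.85, 0.84, 0.86))
fit_distribution <- function(spec, id = "parameter") {
  if (is_degenerate_spec(spec))
    return(structure(list(family = "fixed", value = spec$base), class = "fitted_dist"))
  m <- spec$base
  s <- (spec$high - spec$low) / 3.92
  v <- s^2
  out <- switch(spec$family,
    uniform = list(family = "uniform", min = spec$low, max = spec$high),
    gamma = list(family = "gamma", shape = m^2 / v, scale = v / m),
    beta = ,
    dirichlet_row_member = {
      if (m <= 0 || m >= 1)
        stop(sprintf("%s: beta fit requires mean strictly inside (0, 1), got %g", id, m))
      if (m * (1 - m) <= v)
        stop(sprintf(
          "%s: implied variance %g is infeasible for a beta with mean %g", id, v, m))
      nu <- m * (1 - m) / v - 1
      list(family = "beta", shape1 = m * nu, shape2 = (1 - m) * nu)
    },
    stop(sprintf("%s: cannot fit family '%s'", id, spec$family)))
  structure(out, class = "fitted_dist")
}

#' Draw random values from a fitted distribution
#'
#' Uses the current R random-number stream; seed control belongs to the
#' caller (see [run_psa()]).
#'
#' @param fit A `fitted_dist` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(fit, n = 1) {
  switch(fit$family,
    fixed = rep(fit$value, n),
    uniform = stats::runif(n, fit$min, fit$max),
    gamma = stats::rgamma(n, shape = fit$shape, scale = fit$scale),
    beta = stats::rbeta(n, fit$shape1, fit$shape2),
    stop("unknown fitted family ", fit$family))
}

# Mean of a fitted distribution (used in tests and diagnostics).
fitted_mean <- function(fit) {
  switch(fit$family,
    fixed = fit$value,
    uniform = (fit$min + fit$max) / 2,
    gamma = fit$shape * fit$scale,
    beta = fit$shape1 / (fit$shape1 + fit$shape2))
}
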
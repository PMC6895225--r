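# Community-conditional hypergeometric null and the stochastic continuity
# correction.
#
# Under the null, the tested node's edge stubs are reassigned without
# replacement into the pool formed by the community boundary edges
# ("successes") and the edges internal to the external set ("failures"), so
# its in-degree is hypergeometric. Because that law is discrete, its CDF
# evaluated at the observation is not uniform; the correction g-hat draws
# uniformly on the CDF step containing the observation, which is exactly
# Uniform[0,1] under the null.

#' Bundle hypergeometric null parameters
#'
#' Mostly used in tests and simulations; scoring code obtains parameters from
#' [external_view()].
#'
#' @param draws number of stubs to place (d_u).
#' @param successes edge pool into the community side.
#' @param failures edge pool internal to the external side.
#' @return `focs_null_params` object (population = successes + failures).
#' @export
null_params <- function(draws, successes, failures) {
  stopifnot(is_count(draws), is_count(successes), is_count(failures))
  structure(list(draws = as.numeric(draws), successes = as.numeric(successes),
                 failures = as.numeric(failures),
                 population = as.numeric(successes + failures)),
            class = "focs_null_params")
}

check_feasible <- function(params) {
  stopifnot(inherits(params, "focs_null_params"))
  if (params$draws > params$population) {
    stop_focs(sprintf(
      "infeasible null: node has %g stubs but the external pool has only %g",
      params$draws, params$population), class = "focs_infeasible_error")
  }
  invisible(params)
}

#' Support of the null in-degree distribution
#' @param params a `focs_null_params`.
#' @return integer vector `c(min, max)` of attainable in-degrees.
#' @export
null_support <- function(params) {
  check_feasible(params)
  c(max(0, params$draws - params$failures),
    min(params$draws, params$successes))
}

#' Null probability mass function of the community in-degree
#'
#' P(in-degree = a) under the community-conditional configuration-model null.
#' Evaluated in log space (log-gamma binomial coefficients) so that edge pools
#' of order 10^6 do not overflow; zero outside the support.
#'
#' @param params a `focs_null_params`.
#' @param a integer in-degree value(s); vectorized.
#' @return probability vector, same length as `a`.
#' @export
null_pmf <- function(params, a) {
  check_feasible(params)
  s <- params$successes; f <- params$failures; k <- params$draws
  supp <- null_support(params)
  out <- numeric(length(a))
  ok <- a >= supp[1L] & a <= supp[2L] & a == floor(a)
  if (any(ok)) {
    out[ok] <- exp(lchoose(s, a[ok]) + lchoose(f, k - a[ok]) -
                     lchoose(s + f, k))
  }
  out
}

#' Null cumulative distribution function
#'
#' g(a) = P(in-degree <= a); 0 below the support, 1 at and above its maximum.
#' Summed over the pmf from the support minimum (the support is at most
#' `draws + 1` wide, so direct summation is exact and cheap).
#'
#' @inheritParams null_pmf
#' @return probability vector, same length as `a`.
#' @export
null_cdf <- function(params, a) {
  check_feasible(params)
  supp <- null_support(params)
  cum <- cumsum(null_pmf(params, supp[1L]:supp[2L]))
  cum <- pmin(cum, 1)
  idx <- pmin(floor(a) - supp[1L] + 1, length(cum))
  out <- numeric(length(a))
  pos <- idx >= 1
  out[pos] <- cum[idx[pos]]
  out
}

#' Stochastic continuity correction of the null CDF
#'
#' One realization of g-hat(a) ~ Uniform[g(a-1), g(a)]. At the support
#' minimum the lower bound is 0 (the step below the support has mass 0).
#' Marginally over the null in-degree, g-hat is exactly Uniform[0,1].
#'
#' @param params a `focs_null_params`.
#' @param a observed in-degree (scalar, inside the support).
#' @param seed optional integer seed; by default the current RNG stream is
#'   used.
#' @param quantile optional fixed uniform deviate in \[0,1\] used in place of
#'   a fresh draw (common-random-numbers support for the iterative scorer).
#' @return list of class `focs_corrected_quantile` with `value`, `lower`
#'   (g(a-1)), `upper` (g(a)).
#' @export
corrected_quantile <- function(params, a, seed = NULL, quantile = NULL) {
  check_feasible(params)
  supp <- null_support(params)
  if (length(a) != 1L || a != floor(a) || a < supp[1L] || a > supp[2L]) {
    stop_focs(sprintf(
      "observed in-degree %s outside the null support [%g, %g]",
      paste(a, collapse = ","), supp[1L], supp[2L]),
      class = "focs_impossible_observation")
  }
  bounds <- null_cdf(params, c(a - 1, a))
  lower <- bounds[1L]; upper <- bounds[2L]
  u <- if (is.null(quantile)) {
    with_seed_or_stream(seed, stats::runif(1L))
  } else {
    stopifnot(quantile >= 0, quantile <= 1)
    quantile
  }
  structure(list(value = lower + u * (upper - lower),
                 lower = lower, upper = upper),
            class = "focs_corrected_quantile")
}

#' Sample in-degrees from the null
#'
#' Draws from the hypergeometric null law; intended for simulation and oracle
#' testing of the edge-reassignment model, not for scoring.
#'
#' @param params a `focs_null_params`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return integer vector of length `n`.
#' @export
sample_null_indegree <- function(params, n = 1L, seed = NULL) {
  check_feasible(params)
  with_seed_or_stream(seed,
    stats::rhyper(n, m = params$successes, n = params$failures,
                  k = params$draws))
}
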
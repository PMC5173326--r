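# Closed-form belief algebra: published-outcome probabilities, posteriors on
# the publication lattice, log-odds increments, and expected drift.

#' Probability that a published test of a true claim is positive
#'
#' Experiments on a true claim succeed with probability `1 - beta` and are
#' then published at rate `rho1`; failures occur with probability `beta` and
#' are published at rate `rho0`. Conditional on publication, the probability
#' that the reported outcome is positive is
#' `(1 - beta) * rho1 / ((1 - beta) * rho1 + beta * rho0)`.
#'
#' @param params a [model_params()] object.
#' @return A probability in (0, 1]; equals `1 - beta` when there is no
#'   publication bias (`rho0 == rho1`) and 1 when negatives are never
#'   published (`rho0 == 0`).
#' @seealso [omega_false()], [expected_drift()]
#' @export
omega_true <- function(params) {
  stopifnot(inherits(params, "model_params"))
  s <- 1 - params$beta
  s * params$rho1 / (s * params$rho1 + (1 - s) * params$rho0)
}

#' Probability that a published test of a false claim is positive
#'
#' Same construction as [omega_true()] but for a false claim, whose
#' experiments come out positive at the *actual* false positive rate:
#' `alpha_act * rho1 / (alpha_act * rho1 + (1 - alpha_act) * rho0)`.
#' With `alpha_act == alpha` (the default) this is the plain biased-publication
#' model; with `alpha_act > alpha` it is the p-hacked variant.
#'
#' @inheritParams omega_true
#' @return A probability in (0, 1]; equals `alpha_act` without publication
#'   bias and 1 when `rho0 == 0`.
#' @export
omega_false <- function(params) {
  stopifnot(inherits(params, "model_params"))
  s <- params$alpha_act
  s * params$rho1 / (s * params$rho1 + (1 - s) * params$rho0)
}

# omega for either truth value at an arbitrary effective rho0 (vectorized in
# rho0); used by the absorbing chain under belief-linked policies.
omega_at <- function(params, truth, rho0) {
  s <- positive_rate(params, truth)
  s * params$rho1 / (s * params$rho1 + (1 - s) * rho0)
}

#' Log-odds increments per published outcome
#'
#' Readers update beliefs with the nominal error rates and no awareness of
#' publication bias, so each published positive shifts the log odds of belief
#' by `d1 = log((1 - beta)/alpha)` > 0 and each published negative by
#' `d0 = log(beta/(1 - alpha))` < 0. Under p-hacking the increments still use
#' the nominal `alpha`: the inflation of the actual rate changes how often
#' positives appear, not how readers weigh them.
#'
#' @inheritParams omega_true
#' @return An object of class `"log_odds_steps"`: list with elements `d1`
#'   (positive) and `d0` (negative).
#' @export
log_odds_steps <- function(params) {
  stopifnot(inherits(params, "model_params"))
  structure(list(d1 = log((1 - params$beta) / params$alpha),
                 d0 = log(params$beta / (1 - params$alpha))),
            class = "log_odds_steps")
}

#' @export
print.log_odds_steps <- function(x, ...) {
  cat(sprintf("Log-odds increments: d1 = %+.6f per positive, d0 = %+.6f per negative\n",
              x$d1, x$d0))
  invisible(x)
}

# Lattice log odds after k publications of which y were positive (vectorized
# in y and k).
lattice_log_odds <- function(params, k, y, steps = log_odds_steps(params)) {
  stats::qlogis(params$q0) + y * steps$d1 + (k - y) * steps$d0
}

check_ky <- function(k, y) {
  if (any(k < 0) || any(k != floor(k)) || any(y != floor(y)))
    abort_validation("'k' and 'y' must be nonnegative integers")
  if (any(y < 0) || any(y > k))
    abort_validation("need 0 <= y <= k")
}

#' Naive posterior belief after k publications
#'
#' The posterior probability that the claim is true given `y` positive
#' results among `k` publications, computed under the (incorrect) assumption
#' that there is no publication bias — i.e. treating published outcomes as
#' raw experimental outcomes with error rates `alpha` (nominal) and `beta`.
#' This is the belief the modeled community actually holds.
#'
#' Evaluated on the log-odds scale,
#' `logit(q) = logit(q0) + y * d1 + (k - y) * d0`, which is exact and avoids
#' the underflow of the product form for large `k`.
#'
#' @inheritParams omega_true
#' @param k number of published results (nonnegative integer; vectorized).
#' @param y number of positive published results, `0 <= y <= k` (vectorized).
#' @return Posterior probability (numeric, recycled to the common length).
#' @examples
#' p <- model_params(alpha = 0.2, beta = 0.4, rho0 = 1, q0 = 0.1,
#'                   tau0 = 0.1, tau1 = 0.9)
#' naive_posterior(p, k = 1, y = 1)  # 0.06 / (0.06 + 0.18) = 0.25
#' @export
naive_posterior <- function(params, k, y) {
  stopifnot(inherits(params, "model_params"))
  check_ky(k, y)
  stats::plogis(lattice_log_odds(params, k, y))
}

#' Bias-aware posterior belief after k publications
#'
#' The posterior probability that the claim is true given `y` positives among
#' `k` publications when the extent of publication bias is known: published
#' outcomes are Bernoulli with success probability [omega_true()] under truth
#' and [omega_false()] under falsehood, and Bayes' rule gives
#' `wT^y (1-wT)^(k-y) q0 / (wT^y (1-wT)^(k-y) q0 + wF^y (1-wF)^(k-y) (1-q0))`.
#' Coincides with [naive_posterior()] when `rho0 == rho1`.
#'
#' The negative-outcome likelihood ratio `(1-wT)/(1-wF)` is computed in the
#' algebraically reduced form `beta (a rho1 + (1-a) rho0) /
#' ((1-a) ((1-beta) rho1 + beta rho0))` with `a = alpha_act`, in which `rho0`
#' cancels from the indeterminate 0/0 at `rho0 = 0`.
#'
#' @inheritParams naive_posterior
#' @return Posterior probability (numeric, recycled to the common length).
#' @export
informed_posterior <- function(params, k, y) {
  stopifnot(inherits(params, "model_params"))
  check_ky(k, y)
  a <- params$alpha_act; b <- params$beta
  r0 <- params$rho0; r1 <- params$rho1
  lr1 <- log(omega_true(params)) - log(omega_false(params))
  lr0 <- log(b) + log(a * r1 + (1 - a) * r0) -
         log(1 - a) - log((1 - b) * r1 + b * r0)
  stats::plogis(stats::qlogis(params$q0) + y * lr1 + (k - y) * lr0)
}

#' Belief state on the publication lattice
#'
#' A node of the belief lattice: `k` published results of which `y` were
#' positive, with the community's (naive) belief and its log odds.
#'
#' @inheritParams naive_posterior
#' @return An object of class `"belief_state"`: list with fields `k`, `y`,
#'   `belief` and `log_odds`.
#' @export
belief_state <- function(params, k, y) {
  stopifnot(inherits(params, "model_params"))
  check_ky(k, y)
  stopifnot(length(k) == 1L, length(y) == 1L)
  L <- lattice_log_odds(params, k, y)
  structure(list(k = as.integer(k), y = as.integer(y),
                 belief = stats::plogis(L), log_odds = L),
            class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("Belief state: k = %d publications, y = %d positive; q = %.6g (log odds %+.4f)\n",
              x$k, x$y, x$belief, x$log_odds))
  invisible(x)
}

#' Expected log-odds drift per published result
#'
#' The mean change in the log odds of belief caused by one published result,
#' conditional on the truth of the claim: `d1 * w + d0 * (1 - w)` with
#' `w = ` [omega_true()] for a true claim and [omega_false()] for a false one.
#' A false claim with positive drift is carried toward canonization on
#' average; the drift becomes positive when the negative publication rate is
#' small enough.
#'
#' @inheritParams omega_true
#' @param truth `"false"` or `"true"` — which conditional law to use.
#' @return Expected log-odds change per publication (scalar).
#' @seealso [drift_zero_rho0()] for the zero crossing in `rho0`.
#' @export
expected_drift <- function(params, truth = c("false", "true")) {
  stopifnot(inherits(params, "model_params"))
  truth <- match.arg(truth)
  st <- log_odds_steps(params)
  w <- if (truth == "true") omega_true(params) else omega_false(params)
  st$d1 * w + st$d0 * (1 - w)
}

#' Negative publication rate at which expected drift vanishes
#'
#' Solves `d1 * w + d0 * (1 - w) = 0` for the published-positive probability
#' `w* = -d0 / (d1 - d0)` and inverts the publication-bias map to the unique
#' `rho0* = s * rho1 * (1 - w*) / ((1 - s) * w*)`, where `s` is the raw
#' positive-outcome rate (`alpha_act` for a false claim, `1 - beta` for a
#' true one). Below `rho0*` the claim drifts toward canonization on average;
#' above it, toward rejection.
#'
#' @inheritParams expected_drift
#' @return The zero-crossing `rho0*`, guaranteed to satisfy
#'   `abs(expected_drift) < 1e-10` when substituted back.
#' @section Errors: Raises a no-root error (class `pubcanon_no_crossing`)
#'   when the drift does not change sign on `(0, rho1]`, i.e. when it is
#'   still positive at `rho0 = rho1` (typical for true claims).
#' @export
drift_zero_rho0 <- function(params, truth = c("false", "true")) {
  stopifnot(inherits(params, "model_params"))
  truth <- match.arg(truth)
  st <- log_odds_steps(params)
  w_star <- -st$d0 / (st$d1 - st$d0)
  s <- positive_rate(params, truth)
  rho0_star <- s * params$rho1 * (1 - w_star) / ((1 - s) * w_star)
  if (!is.finite(rho0_star) || rho0_star <= 0 || rho0_star > params$rho1)
    abort_no_crossing(sprintf(
      "expected drift for a %s claim has no zero on (0, rho1]: rho0* = %g",
      truth, rho0_star))
  check <- expected_drift(update_params(params, rho0 = rho0_star), truth)
  stopifnot(abs(check) < 1e-10)
  rho0_star
}
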
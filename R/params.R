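# Parameter containers and validation for the canonization model.

#' Condition constructors used across the package
#'
#' All user-facing errors carry a subclass of `pubcanon_error` so callers
#' (including the command-line driver) can map failure modes to exit codes.
#'
#' @param msg character message.
#' @name pubcanon-conditions
#' @keywords internal
NULL

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("pubcanon_validation_error", "pubcanon_error")))
}

abort_no_convergence <- function(msg) {
  stop(errorCondition(msg, class = c("pubcanon_no_convergence", "pubcanon_error")))
}

abort_no_crossing <- function(msg) {
  stop(errorCondition(msg, class = c("pubcanon_no_crossing", "pubcanon_error")))
}

check_prob <- function(x, name, open_lower = TRUE, open_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!lo_ok || !hi_ok)
    abort_validation(sprintf("'%s' = %g is outside the %s0, 1%s interval",
                             name, x,
                             if (open_lower) "(" else "[",
                             if (open_upper) ")" else "]"))
  as.numeric(x)
}

# Absolute tolerance for log-odds comparisons against the evidentiary
# thresholds; lattice points landing numerically on a boundary are classified
# deterministically as interior.
LOG_ODDS_TOL <- 1e-12

#' Model parameters for the claim-canonization process
#'
#' Bundles every scalar parameter of the publication/belief model: the error
#' rates of a single experiment, the result-dependent publication rates, the
#' community's prior belief, and the evidentiary standards at which a claim is
#' canonized as fact or rejected as false.
#'
#' The actual false positive rate `alpha_act` defaults to the nominal rate
#' `alpha`. Setting `alpha_act > alpha` models p-hacking and related
#' questionable research practices: experiments on false claims then come up
#' positive at the actual rate, while readers keep updating their beliefs with
#' the nominal rate.
#'
#' Only the ratio of `rho0` to `rho1` matters for the published-outcome
#' process, so `rho1` defaults to 1 and `rho0` is read as a rate relative to
#' it. Values `rho0 > rho1` (negative results more publishable than positive
#' ones) are accepted and flagged via the `grey` field.
#'
#' @param alpha nominal false positive rate of a single experiment, in (0,1);
#'   this is the rate readers use when updating beliefs.
#' @param beta false negative rate of a single experiment, in (0,1).
#' @param rho0 publication rate of negative results, relative to `rho1`;
#'   nonnegative.
#' @param q0 initial community belief that the claim is true, in (0,1).
#' @param tau0 rejection standard: the claim is discarded once belief falls
#'   below `tau0`.
#' @param tau1 canonization standard: the claim becomes fact once belief
#'   exceeds `tau1`. Requires `0 < tau0 < tau1 < 1`.
#' @param rho1 publication rate of positive results (reference scale,
#'   default 1).
#' @param alpha_act actual false positive rate, `>= alpha`; defaults to
#'   `alpha` (no p-hacking).
#' @param epsilon truncation tolerance for the absorbing-chain recursion: the
#'   computation stops once the undecided probability mass is at most
#'   `epsilon`. Default `1e-4`.
#'
#' @return An object of class `"model_params"`: a validated list with the
#'   fields above plus `grey` (logical, `TRUE` when `rho0 > rho1`).
#'
#' @details Validation enforces `1 - beta > alpha` and `1 - beta > alpha_act`
#'   (a true claim must be more likely than a false one to produce a positive
#'   result, so that a published positive raises belief), and
#'   `alpha_act >= alpha` (p-hacking can only inflate the false positive
#'   rate).
#'
#' @examples
#' p <- model_params(alpha = 0.05, beta = 0.2, rho0 = 0.5,
#'                   q0 = 0.5, tau0 = 0.001, tau1 = 0.999)
#' omega_true(p)
#' @export
model_params <- function(alpha, beta, rho0, q0, tau0, tau1,
                         rho1 = 1, alpha_act = alpha, epsilon = 1e-4) {
  alpha     <- check_prob(alpha, "alpha")
  alpha_act <- check_prob(alpha_act, "alpha_act")
  beta      <- check_prob(beta, "beta")
  q0        <- check_prob(q0, "q0")
  tau0      <- check_prob(tau0, "tau0")
  tau1      <- check_prob(tau1, "tau1")
  if (!is.numeric(rho0) || length(rho0) != 1L || !is.finite(rho0) || rho0 < 0)
    abort_validation("'rho0' must be a single finite nonnegative number")
  if (!is.numeric(rho1) || length(rho1) != 1L || !is.finite(rho1) || rho1 <= 0)
    abort_validation("'rho1' must be a single finite positive number")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0)
    abort_validation("'epsilon' must be a single finite positive number")
  if (tau0 >= tau1)
    abort_validation(sprintf("need tau0 < tau1 (got tau0 = %g, tau1 = %g)", tau0, tau1))
  if (1 - beta <= alpha)
    abort_validation(sprintf(
      "uninformative test: need 1 - beta > alpha (got alpha = %g, beta = %g)",
      alpha, beta))
  if (1 - beta <= alpha_act)
    abort_validation(sprintf(
      "uninformative test: need 1 - beta > alpha_act (got alpha_act = %g, beta = %g)",
      alpha_act, beta))
  if (alpha_act < alpha)
    abort_validation(sprintf(
      "p-hacking can only inflate the false positive rate: need alpha_act >= alpha (got %g < %g)",
      alpha_act, alpha))
  structure(
    list(alpha = alpha, alpha_act = alpha_act, beta = beta,
         rho0 = as.numeric(rho0), rho1 = as.numeric(rho1),
         q0 = q0, tau0 = tau0, tau1 = tau1, epsilon = epsilon,
         grey = rho0 > rho1),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Canonization model parameters\n")
  cat(sprintf("  error rates:   alpha = %g (actual %g), beta = %g\n",
              x$alpha, x$alpha_act, x$beta))
  cat(sprintf("  publication:   rho1 = %g, rho0 = %g%s\n",
              x$rho1, x$rho0,
              if (x$grey) "  [rho0 > rho1: negatives favoured]" else ""))
  cat(sprintf("  belief:        q0 = %g, standards tau0 = %g, tau1 = %g\n",
              x$q0, x$tau0, x$tau1))
  cat(sprintf("  truncation:    epsilon = %g\n", x$epsilon))
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a revalidated copy of `params` with the named fields replaced.
#' When `alpha` is changed and `alpha_act` is not supplied explicitly,
#' `alpha_act` follows `alpha` (the no-p-hacking default).
#'
#' @param params a [model_params()] object.
#' @param ... named scalar fields to replace.
#' @return A new `"model_params"` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  new <- list(...)
  bad <- setdiff(names(new),
                 c("alpha", "alpha_act", "beta", "rho0", "rho1",
                   "q0", "tau0", "tau1", "epsilon"))
  if (length(bad))
    abort_validation(paste0("unknown parameter field(s): ",
                            paste(bad, collapse = ", ")))
  if ("alpha" %in% names(new) && !("alpha_act" %in% names(new)) &&
      params$alpha_act == params$alpha)
    new$alpha_act <- new$alpha
  full <- utils::modifyList(params[c("alpha", "alpha_act", "beta", "rho0",
                                     "rho1", "q0", "tau0", "tau1", "epsilon")],
                            new)
  do.call(model_params, full)
}

#' Truth value of a claim
#'
#' Claims are either ontologically true or false; the published-outcome law
#' differs between the two. Most functions take the truth value as the string
#' `"false"` or `"true"`; this helper normalizes and validates it.
#'
#' @param truth `"false"` or `"true"` (partial matching allowed).
#' @return The matched string.
#' @export
truth_value <- function(truth = c("false", "true")) {
  match.arg(truth)
}

#' Publication policy for negative results
#'
#' In the constant policy, negative results are published at the fixed rate
#' `rho0` from the parameter set. In the belief-linked policy, the negative
#' publication rate rises linearly with the community's current belief `q`:
#' `rho0(q) = rho_b + q * (1 - rho_b)`, from a baseline `rho_b` when the claim
#' is not believed up to 1 when it is fully believed — contradicting a
#' well-established claim is itself noteworthy.
#'
#' @param mode `"constant"` or `"belief_linked"`.
#' @param rho_b baseline negative publication rate in \[0, 1\]; required for
#'   the belief-linked mode, ignored otherwise.
#' @return An object of class `"publication_policy"`.
#' @examples
#' publication_policy()                       # constant rho0
#' publication_policy("belief_linked", 0.05)  # baseline 5%
#' @export
publication_policy <- function(mode = c("constant", "belief_linked"),
                               rho_b = NULL) {
  mode <- match.arg(mode)
  if (mode == "belief_linked") {
    if (is.null(rho_b))
      abort_validation("belief_linked policy requires 'rho_b'")
    rho_b <- check_prob(rho_b, "rho_b", open_lower = FALSE, open_upper = FALSE)
  } else {
    rho_b <- NA_real_
  }
  structure(list(mode = mode, rho_b = rho_b), class = "publication_policy")
}

#' @export
print.publication_policy <- function(x, ...) {
  if (x$mode == "constant")
    cat("Publication policy: constant rho0\n")
  else
    cat(sprintf("Publication policy: belief-linked, rho0(q) = %g + q * %g\n",
                x$rho_b, 1 - x$rho_b))
  invisible(x)
}

#' Effective negative publication rate under a policy
#'
#' @param policy a [publication_policy()] object.
#' @param params a [model_params()] object.
#' @param q current belief (vectorized).
#' @return Numeric vector of negative publication rates, one per belief.
#' @export
rho0_effective <- function(policy, params, q) {
  stopifnot(inherits(policy, "publication_policy"),
            inherits(params, "model_params"))
  if (policy$mode == "constant") rep_len(params$rho0, length(q))
  else policy$rho_b + q * (1 - policy$rho_b)
}

# Probability that a single experiment comes out positive: depends on the
# claim's truth; false claims use the ACTUAL false positive rate.
positive_rate <- function(params, truth) {
  if (truth == "true") 1 - params$beta else params$alpha_act
}
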
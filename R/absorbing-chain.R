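# Exact first-passage computation on the publication lattice.
#
# After k publications the state is y, the number of positives; belief is a
# deterministic function of (k, y). The interior (undecided) states carry
# probability mass forward one publication at a time; mass crossing an
# evidentiary standard is absorbed and recorded in the first-passage series.

# Interior test on the log-odds scale. Equality with a threshold counts as
# interior (the undecided band is the closed interval [tau0, tau1]).
threshold_log_odds <- function(params) {
  c(lo = stats::qlogis(params$tau0), hi = stats::qlogis(params$tau1))
}

#' Partition lattice states at publication k
#'
#' Splits the state space `y = 0, ..., k` into canonized states (belief
#' strictly above `tau1`), rejected states (belief strictly below `tau0`),
#' and the undecided interior (belief in the closed interval
#' `[tau0, tau1]`). Because belief is monotone in `y` at fixed `k`, each set
#' is a contiguous run of `y` values. Comparisons are done in log odds with
#' an absolute tie tolerance of 1e-12, so states landing numerically on a
#' boundary are classified (as interior) deterministically.
#'
#' @inheritParams naive_posterior
#' @param k number of publications (single nonnegative integer).
#' @return An object of class `"state_partition"`: list with integer vectors
#'   `canon`, `interior`, `reject` and the publication count `k`.
#' @export
partition_states <- function(params, k) {
  stopifnot(inherits(params, "model_params"),
            length(k) == 1L, k >= 0, k == floor(k))
  y <- 0:k
  L <- lattice_log_odds(params, k, y)
  thr <- threshold_log_odds(params)
  canon  <- y[L > thr["hi"] + LOG_ODDS_TOL]
  reject <- y[L < thr["lo"] - LOG_ODDS_TOL]
  structure(list(k = as.integer(k),
                 canon = as.integer(canon),
                 interior = as.integer(setdiff(y, c(canon, reject))),
                 reject = as.integer(reject)),
            class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "-"
  cat(sprintf("State partition at k = %d\n  canonized y: %s\n  interior  y: %s\n  rejected  y: %s\n",
              x$k, fmt(x$canon), fmt(x$interior), fmt(x$reject)))
  invisible(x)
}

# Internal single step of the recursion, vectorized over the interior
# frontier. `y` and `p` are parallel vectors (states and their mass at k);
# returns list(y, p) over the reachable states at k + 1, unpartitioned.
# Under a belief-linked policy the published-positive probability omega is
# state dependent, evaluated at the belief of the SOURCE state.
step_frontier <- function(y, p, k, params, truth, policy, steps) {
  q <- stats::plogis(lattice_log_odds(params, k, y, steps))
  w <- omega_at(params, truth, rho0_effective(policy, params, q))
  y_out <- min(y):(max(y) + 1L)
  m <- numeric(length(y_out))
  i_stay <- match(y, y_out)
  i_up <- i_stay + 1L
  # accumulate with care: i_up of one state equals i_stay of the next
  m[i_stay] <- m[i_stay] + p * (1 - w)
  up <- p * w
  for (j in seq_along(y)) m[i_up[j]] <- m[i_up[j]] + up[j]
  list(y = y_out, p = m)
}

#' One forward step of the interior-mass recursion
#'
#' Propagates the undecided probability mass at publication `k` one step: a
#' state with `y` positives moves to `y + 1` with the published-positive
#' probability `omega` and stays at `y` (gaining a published negative)
#' otherwise. Under the belief-linked policy `omega` differs by source state,
#' since the negative publication rate depends on the belief held *before*
#' the new publication. Total mass is conserved; partitioning of the
#' resulting states happens separately (see [partition_states()]).
#'
#' @inheritParams expected_drift
#' @param mass named numeric vector: interior probability mass at `k`, with
#'   names giving the `y` values. Support must lie inside the interior set.
#' @param k current publication count.
#' @param policy a [publication_policy()].
#' @return Named numeric vector of mass over the reachable `y` at `k + 1`.
#' @export
forward_step <- function(mass, k, params, truth = c("false", "true"),
                         policy = publication_policy()) {
  stopifnot(inherits(params, "model_params"), is.numeric(mass),
            !is.null(names(mass)))
  truth <- match.arg(truth)
  y <- as.integer(names(mass))
  part <- partition_states(params, k)
  if (!all(y %in% part$interior))
    abort_validation("forward_step: input mass has support outside the interior set")
  out <- step_frontier(y, as.numeric(mass), k, params, truth, policy,
                       log_odds_steps(params))
  stats::setNames(out$p, out$y)
}

#' Exact canonization and rejection probabilities
#'
#' Runs the absorbing-chain recursion for a claim of the given truth value:
#' starting from unit mass at the prior belief, the interior mass is stepped
#' forward one publication at a time, and mass crossing the canonization
#' (rejection) standard at step `k` is accumulated into the first-passage
#' series `phi_canonize[k]` (`phi_reject[k]`). Iteration stops at the horizon
#' `k_star`, the smallest `k` at which the undecided mass is at most
#' `epsilon`; that residual is reported, never silently folded into either
#' absorption probability.
#'
#' A prior already beyond a standard (`q0 > tau1` or `q0 < tau0`) is treated
#' as immediate absorption at `k_star = 0`.
#'
#' @inheritParams forward_step
#' @param max_k safety cap on the number of publications (default 1e5);
#'   reaching it with undecided mass above `epsilon` raises a
#'   non-convergence error reporting the residual.
#' @return An object of class `"absorption_result"` with fields
#'   `p_canonize`, `p_reject`, `p_undecided` (summing to 1), `k_star`,
#'   `phi_canonize` and `phi_reject` (first-passage probabilities, length
#'   `k_star`), `truth`, `params`, `policy`.
#' @examples
#' p <- model_params(alpha = 0.2, beta = 0.4, rho0 = 1, q0 = 0.5,
#'                   tau0 = 0.4, tau1 = 0.6)
#' absorption_probabilities(p, "false")  # canonized with probability 0.2
#' @export
absorption_probabilities <- function(params, truth = c("false", "true"),
                                     policy = publication_policy(),
                                     max_k = 100000L) {
  stopifnot(inherits(params, "model_params"),
            inherits(policy, "publication_policy"))
  truth <- match.arg(truth)
  steps <- log_odds_steps(params)
  thr <- threshold_log_odds(params)
  L0 <- stats::qlogis(params$q0)

  finish <- function(pc, pr, pu, k_star, phi_c, phi_r) {
    structure(list(p_canonize = pc, p_reject = pr, p_undecided = pu,
                   k_star = as.integer(k_star),
                   phi_canonize = phi_c, phi_reject = phi_r,
                   truth = truth, params = params, policy = policy),
              class = "absorption_result")
  }
  if (L0 > thr["hi"] + LOG_ODDS_TOL)
    return(finish(1, 0, 0, 0L, numeric(0), numeric(0)))
  if (L0 < thr["lo"] - LOG_ODDS_TOL)
    return(finish(0, 1, 0, 0L, numeric(0), numeric(0)))

  y <- 0L; p <- 1       # interior frontier at k = 0
  cap <- 2048L
  phi_c <- numeric(cap); phi_r <- numeric(cap)
  k <- 0L; residual <- 1
  while (residual > params$epsilon && k < max_k) {
    out <- step_frontier(y, p, k, params, truth, policy, steps)
    k <- k + 1L
    if (k > cap) {           # grow first-passage storage geometrically
      cap <- cap * 2L
      length(phi_c) <- cap; length(phi_r) <- cap
      phi_c[is.na(phi_c)] <- 0; phi_r[is.na(phi_r)] <- 0
    }
    L <- L0 + out$y * steps$d1 + (k - out$y) * steps$d0
    up <- L > thr["hi"] + LOG_ODDS_TOL
    dn <- L < thr["lo"] - LOG_ODDS_TOL
    phi_c[k] <- sum(out$p[up])
    phi_r[k] <- sum(out$p[dn])
    keep <- !(up | dn) & out$p > 0
    y <- out$y[keep]; p <- out$p[keep]
    residual <- sum(p)
  }
  if (residual > params$epsilon)
    abort_no_convergence(sprintf(
      "absorbing chain did not converge within %d publications (undecided mass %.3g > epsilon %.3g)",
      max_k, residual, params$epsilon))
  phi_c <- phi_c[seq_len(k)]; phi_r <- phi_r[seq_len(k)]
  finish(sum(phi_c), sum(phi_r), residual, k, phi_c, phi_r)
}

#' @export
print.absorption_result <- function(x, ...) {
  cat(sprintf("Absorption probabilities (%s claim)\n", x$truth))
  cat(sprintf("  canonized as fact: %.6g\n  rejected as false: %.6g\n",
              x$p_canonize, x$p_reject))
  cat(sprintf("  undecided (residual): %.3g after k* = %d publications\n",
              x$p_undecided, x$k_star))
  invisible(x)
}

#' Mean number of publications to absorption
#'
#' The mean of the first-passage time over the absorbed trajectories,
#' `sum(k * (phi_canonize[k] + phi_reject[k])) / (1 - p_undecided)`. Because
#' the recursion truncates at `k_star`, this is a (slight) lower bound on the
#' true expectation; the attribute `"truncated"` flags this.
#'
#' @param result an [absorption_probabilities()] result.
#' @return Expected publications at absorption (0 for an immediately
#'   absorbed prior), with attribute `"truncated" = TRUE`.
#' @export
expected_publications <- function(result) {
  stopifnot(inherits(result, "absorption_result"))
  if (result$k_star == 0L) return(structure(0, truncated = TRUE))
  k <- seq_len(result$k_star)
  structure(sum(k * (result$phi_canonize + result$phi_reject)) /
              (1 - result$p_undecided),
            truncated = TRUE)
}
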
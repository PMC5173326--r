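# Seeded stochastic simulator of the experiment -> publication -> belief
# process. Serves as an independent oracle for the exact recursion: it draws
# the experiment outcome and the publication decision as separate Bernoulli
# events, so unpublished experiments are counted even though they never move
# belief.

# Simulation treats rho0 and rho1 as Bernoulli probabilities, so unlike the
# exact engine (where only the ratio matters) they must not exceed 1.
check_simulable <- function(params) {
  if (params$rho1 > 1 || params$rho0 > 1)
    abort_validation(
      "simulation requires rho1 <= 1 and rho0 <= 1 (publication rates are per-result probabilities here); rescale the pair, only their ratio affects the published-outcome law")
}

# Core kernel: runs one trajectory with the current RNG state.
# record = TRUE keeps the outcome/belief path for trajectory objects;
# record = FALSE only tracks counts (used by ensemble estimation).
sim_kernel <- function(params, truth, policy, max_experiments, record) {
  steps <- log_odds_steps(params)
  thr <- threshold_log_odds(params)
  lo <- thr[["lo"]]; hi <- thr[["hi"]]
  s <- positive_rate(params, truth)
  rho1 <- params$rho1
  constant <- policy$mode == "constant"
  rho0_const <- params$rho0
  rho_b <- policy$rho_b

  L <- stats::qlogis(params$q0)
  k <- 0L; y <- 0L; n_exp <- 0L
  outcomes <- if (record) integer(0) else NULL
  beliefs  <- if (record) numeric(0) else NULL
  absorbed <- "capped"
  if (L > hi + LOG_ODDS_TOL) absorbed <- "canonized"
  if (L < lo - LOG_ODDS_TOL) absorbed <- "rejected"
  while (absorbed == "capped" && n_exp < max_experiments) {
    n_exp <- n_exp + 1L
    positive <- stats::runif(1) < s
    pub_prob <- if (positive) rho1
                else if (constant) rho0_const
                else rho_b + stats::plogis(L) * (1 - rho_b)
    if (stats::runif(1) < pub_prob) {
      k <- k + 1L
      if (positive) { y <- y + 1L; L <- L + steps$d1 } else L <- L + steps$d0
      if (record) {
        outcomes <- c(outcomes, if (positive) 1L else 0L)
        beliefs <- c(beliefs, stats::plogis(L))
      }
      if (L > hi + LOG_ODDS_TOL) absorbed <- "canonized"
      else if (L < lo - LOG_ODDS_TOL) absorbed <- "rejected"
    }
  }
  list(absorbed = absorbed, t_absorb = k, y = y,
       n_experiments = n_exp, outcomes = outcomes, beliefs = beliefs)
}

#' Simulate one publication trajectory
#'
#' Draws experiments on the claim one at a time (positive with probability
#' `1 - beta` for a true claim, `alpha_act` for a false one), publishes each
#' with probability `rho1` (positive result) or the policy's `rho0(q)`
#' (negative result, evaluated at the belief held before the publication),
#' and updates the community's naive belief only on publication, using the
#' nominal error rates. The trajectory ends when belief crosses an
#' evidentiary standard, or is reported as capped if `max_experiments`
#' experiments pass first.
#'
#' @inheritParams forward_step
#' @param seed integer seed; the same seed reproduces the trajectory exactly.
#' @param max_experiments cap on total experiments (default 1e6).
#' @return An object of class `"trajectory"`: list with `outcomes` (1 =
#'   published positive, 0 = published negative, in order), `beliefs` (naive
#'   belief after each publication), `absorbed` (`"canonized"`, `"rejected"`
#'   or `"capped"`), `t_absorb` (publications at absorption),
#'   `n_experiments` (total experiments, published or not), `truth`.
#' @export
simulate_trajectory <- function(params, truth = c("false", "true"),
                                policy = publication_policy(),
                                seed, max_experiments = 1e6) {
  stopifnot(inherits(params, "model_params"),
            inherits(policy, "publication_policy"))
  truth <- match.arg(truth)
  check_simulable(params)
  set.seed(as.integer(seed))
  out <- sim_kernel(params, truth, policy, max_experiments, record = TRUE)
  structure(list(outcomes = out$outcomes, beliefs = out$beliefs,
                 absorbed = out$absorbed, t_absorb = out$t_absorb,
                 n_experiments = out$n_experiments, truth = truth),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s claim): %s after %d publications (%d experiments)\n",
              x$truth, x$absorbed, x$t_absorb, x$n_experiments))
  if (length(x$beliefs))
    cat(sprintf("  final belief %.6g; %d positive of %d published\n",
                x$beliefs[length(x$beliefs)], sum(x$outcomes), x$t_absorb))
  invisible(x)
}

#' Monte-Carlo estimate of the absorption probabilities
#'
#' Simulates `n_reps` independent trajectories and reports the fraction
#' canonized, rejected, and capped, with binomial standard errors. Trajectory
#' `i` runs on its own substream seeded by `seed + i - 1`, so the ensemble is
#' reproducible and independent of evaluation order.
#'
#' @inheritParams simulate_trajectory
#' @param n_reps number of trajectories (`>= 1`).
#' @return An object of class `"absorption_estimate"`: list with `n_reps`,
#'   `counts` (named: canonized/rejected/capped), `fractions`, `se`
#'   (binomial standard errors), `mean_t_absorb`, `pos_published` and
#'   `neg_published` (ensemble totals of published outcomes, for drift
#'   checks), `mean_experiments`.
#' @examples
#' p <- model_params(alpha = 0.2, beta = 0.4, rho0 = 1, q0 = 0.5,
#'                   tau0 = 0.4, tau1 = 0.6)
#' estimate_absorption(p, "false", n_reps = 1000, seed = 1)
#' @export
estimate_absorption <- function(params, truth = c("false", "true"),
                                policy = publication_policy(),
                                n_reps, seed, max_experiments = 1e6) {
  stopifnot(inherits(params, "model_params"),
            inherits(policy, "publication_policy"),
            n_reps >= 1)
  truth <- match.arg(truth)
  check_simulable(params)
  counts <- c(canonized = 0L, rejected = 0L, capped = 0L)
  tot_t <- 0; tot_pos <- 0; tot_exp <- 0
  base <- as.numeric(seed)
  for (i in seq_len(n_reps)) {
    set.seed(as.integer((base + i - 1) %% 2147483646) + 1L)
    out <- sim_kernel(params, truth, policy, max_experiments, record = FALSE)
    counts[out$absorbed] <- counts[out$absorbed] + 1L
    tot_t <- tot_t + out$t_absorb
    tot_pos <- tot_pos + out$y
    tot_exp <- tot_exp + out$n_experiments
  }
  frac <- counts / n_reps
  structure(list(n_reps = as.integer(n_reps),
                 counts = counts,
                 fractions = frac,
                 se = sqrt(frac * (1 - frac) / n_reps),
                 mean_t_absorb = tot_t / n_reps,
                 pos_published = tot_pos,
                 neg_published = tot_t - tot_pos,
                 mean_experiments = tot_exp / n_reps,
                 truth = truth),
            class = "absorption_estimate")
}

#' @export
print.absorption_estimate <- function(x, ...) {
  cat(sprintf("Monte-Carlo absorption estimate (%s claim, n = %d)\n",
              x$truth, x$n_reps))
  for (nm in names(x$fractions))
    cat(sprintf("  %-9s %.4f (SE %.4f)\n", nm, x$fractions[nm], x$se[nm]))
  cat(sprintf("  mean publications to absorption %.2f; mean experiments %.2f\n",
              x$mean_t_absorb, x$mean_experiments))
  invisible(x)
}
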
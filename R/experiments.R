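# Parameter sweeps over the exact engine: negative publication rate, prior
# belief, evidentiary standards, drift curves, belief-linked policies, and
# the registered-trial worked example.

default_rho0_grid <- function() seq(0.01, 1, by = 0.01)
default_q0_grid <- function() seq(0.02, 0.98, by = 0.02)

check_grid <- function(grid, name = "grid") {
  if (!is.numeric(grid) || !length(grid) || any(!is.finite(grid)))
    abort_validation(sprintf("'%s' must be a nonempty finite numeric vector", name))
  if (is.unsorted(grid, strictly = TRUE))
    abort_validation(sprintf("'%s' must be strictly increasing", name))
  as.numeric(grid)
}

# Run the exact engine for both truth values and return a one-row data frame.
absorb_row <- function(params, policy = publication_policy(), max_k = 100000L) {
  rf <- absorption_probabilities(params, "false", policy, max_k)
  rt <- absorption_probabilities(params, "true", policy, max_k)
  data.frame(p_canonize_false = rf$p_canonize,
             p_canonize_true = rt$p_canonize,
             p_reject_false = rf$p_reject,
             p_reject_true = rt$p_reject,
             k_star = max(rf$k_star, rt$k_star),
             residual = max(rf$p_undecided, rt$p_undecided))
}

new_sweep <- function(df, axis, params, policy) {
  structure(df, axis = axis, params = params, policy = policy,
            class = c("sweep_result", "data.frame"))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d points)\n", attr(x, "axis"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}

#' Sweep the negative publication rate
#'
#' Computes the exact canonization and rejection probabilities of true and
#' false claims at each value of the negative publication rate `rho0` on the
#' grid, holding every other parameter fixed. This is the central experiment
#' of the model: below a threshold `rho0`, false claims are likely to be
#' canonized as fact. P-hacked parameter sets (`alpha_act > alpha`) run
#' through the same path.
#'
#' @inheritParams expected_drift
#' @param grid strictly increasing vector of `rho0` values in (0, 1]
#'   (default `seq(0.01, 1, 0.01)`).
#' @param max_k safety cap passed to [absorption_probabilities()].
#' @return A `"sweep_result"` data frame with columns `rho0`,
#'   `p_canonize_false`, `p_canonize_true`, `p_reject_false`,
#'   `p_reject_true`, `k_star`, `residual`; the parameter snapshot is
#'   attached as attributes `params` and `policy`.
#' @export
sweep_rho0 <- function(params, grid = default_rho0_grid(), max_k = 100000L) {
  stopifnot(inherits(params, "model_params"))
  grid <- check_grid(grid)
  if (any(grid <= 0))
    abort_validation("rho0 grid values must be positive")
  rows <- lapply(grid, function(r)
    absorb_row(update_params(params, rho0 = r), max_k = max_k))
  df <- cbind(data.frame(rho0 = grid), do.call(rbind, rows))
  new_sweep(df, "rho0", params, publication_policy())
}

#' ROC curve over the negative publication rate
#'
#' For each `rho0` on the grid, pairs the probability that a false claim is
#' (incorrectly) canonized with the probability that a true claim is
#' (correctly) canonized — a receiver-operating-characteristic view of the
#' community's decision process, parameterized by publication bias. Grid
#' points with `rho0 > rho1` are flagged `grey` (negative results more
#' publishable than positives, an unlikely regime).
#'
#' @inheritParams sweep_rho0
#' @return A `"sweep_result"` data frame with columns `rho0`,
#'   `p_canonize_false` (x-coordinate), `p_canonize_true` (y-coordinate),
#'   `grey`.
#' @export
roc_curve <- function(params, grid = default_rho0_grid(), max_k = 100000L) {
  sw <- sweep_rho0(params, grid, max_k)
  df <- data.frame(rho0 = sw$rho0,
                   p_canonize_false = sw$p_canonize_false,
                   p_canonize_true = sw$p_canonize_true,
                   grey = sw$rho0 > params$rho1)
  new_sweep(df, "rho0 (ROC)", params, publication_policy())
}

#' Sweep the initial belief
#'
#' Exact absorption probabilities at each prior belief `q0` on the grid.
#' Grid points outside `[tau0, tau1]` are immediately absorbed (probability
#' 1 of canonization above `tau1`, of rejection below `tau0`). The resulting
#' curves are step-like: the number of net published positives needed to
#' cross a standard is integral, so the probability jumps where that count
#' changes.
#'
#' @inheritParams sweep_rho0
#' @param grid strictly increasing vector of `q0` values in (0, 1).
#' @return A `"sweep_result"` data frame keyed by `q0`.
#' @export
sweep_q0 <- function(params, grid = default_q0_grid(), max_k = 100000L) {
  stopifnot(inherits(params, "model_params"))
  grid <- check_grid(grid)
  rows <- lapply(grid, function(q)
    absorb_row(update_params(params, q0 = q), max_k = max_k))
  df <- cbind(data.frame(q0 = grid), do.call(rbind, rows))
  new_sweep(df, "q0", params, publication_policy())
}

#' Sweep symmetric evidentiary standards
#'
#' Exact absorption probabilities under symmetric standards
#' `(tau0, tau1) = (tau0, 1 - tau0)` for each `tau0` in the list. Exposes
#' the reversal regime: when the false positive rate is high and negative
#' results are rarely published, *stricter* standards (smaller `tau0`) can
#' increase the probability that a false claim is canonized, because the
#' longer evidence-gathering phase gives the positive-biased published
#' record more time to accumulate.
#'
#' @inheritParams sweep_rho0
#' @param tau0_values strictly increasing vector of rejection standards in
#'   (0, 0.5); each is paired with `tau1 = 1 - tau0`.
#' @return A `"sweep_result"` data frame keyed by `tau0` (with `tau1`
#'   column).
#' @export
sweep_tau <- function(params, tau0_values, max_k = 100000L) {
  stopifnot(inherits(params, "model_params"))
  tau0_values <- check_grid(tau0_values, "tau0_values")
  if (any(tau0_values <= 0 | tau0_values >= 0.5))
    abort_validation("'tau0_values' must lie in (0, 0.5)")
  rows <- lapply(tau0_values, function(t0)
    absorb_row(update_params(params, tau0 = t0, tau1 = 1 - t0), max_k = max_k))
  df <- cbind(data.frame(tau0 = tau0_values, tau1 = 1 - tau0_values),
              do.call(rbind, rows))
  new_sweep(df, "tau0 (symmetric standards)", params, publication_policy())
}

#' Expected drift as a function of the negative publication rate
#'
#' Evaluates the expected log-odds change per published result at each
#' `rho0` on the grid, for both truth values. The zero crossing of the
#' false-claim curve equals [drift_zero_rho0()]: below it, the published
#' record pushes belief in a false claim upward on average.
#'
#' @inheritParams sweep_rho0
#' @return A `"sweep_result"` data frame with columns `rho0`, `drift_false`,
#'   `drift_true`.
#' @export
drift_curve <- function(params, grid = default_rho0_grid()) {
  stopifnot(inherits(params, "model_params"))
  grid <- check_grid(grid)
  if (any(grid <= 0))
    abort_validation("rho0 grid values must be positive")
  df <- data.frame(
    rho0 = grid,
    drift_false = vapply(grid, function(r)
      expected_drift(update_params(params, rho0 = r), "false"), 0),
    drift_true = vapply(grid, function(r)
      expected_drift(update_params(params, rho0 = r), "true"), 0))
  new_sweep(df, "rho0 (drift)", params, publication_policy())
}

#' Sweep the baseline rate of a belief-linked publication policy
#'
#' Exact absorption probabilities under the belief-linked policy
#' `rho0(q) = rho_b + q (1 - rho_b)`, for each baseline `rho_b` on the grid.
#' Row-for-row comparable with [sweep_rho0()] on the same grid: the
#' belief-linked policy publishes negatives at least at the baseline rate,
#' and increasingly so as belief grows, which chokes off the runs of
#' unchallenged positives that canonize false claims.
#'
#' @inheritParams sweep_rho0
#' @param grid strictly increasing vector of baseline rates `rho_b` in
#'   (0, 1].
#' @return A `"sweep_result"` data frame keyed by `rho_b`.
#' @export
dynamic_policy_sweep <- function(params, grid = default_rho0_grid(),
                                 max_k = 100000L) {
  stopifnot(inherits(params, "model_params"))
  grid <- check_grid(grid)
  if (any(grid <= 0 | grid > 1))
    abort_validation("rho_b grid values must lie in (0, 1]")
  rows <- lapply(grid, function(rb)
    absorb_row(params, publication_policy("belief_linked", rb), max_k = max_k))
  df <- cbind(data.frame(rho_b = grid), do.call(rbind, rows))
  new_sweep(df, "rho_b (belief-linked policy)", params,
            publication_policy("belief_linked", grid[1]))
}

#' Smallest negative publication rate that defuses a false claim
#'
#' Scans `rho0` over the grid and returns the smallest grid value at which
#' the exact probability of canonizing the false claim is at most
#' `probability_level`. The result is a grid point, not an interpolated
#' root; the grid step is attached as attribute `"grid_step"` so downstream
#' comparisons are honest about resolution.
#'
#' @inheritParams sweep_rho0
#' @param probability_level level in (0, 1) that the canonization
#'   probability must fall to (default 0.5, i.e. "more likely than not").
#' @return The smallest qualifying `rho0` (scalar) with attributes
#'   `"grid_step"` and `"p_at_threshold"`.
#' @section Errors: Raises a no-crossing error (class
#'   `pubcanon_no_crossing`) if the probability stays above the level on the
#'   whole grid.
#' @export
threshold_rho0 <- function(params, probability_level = 0.5,
                           grid = default_rho0_grid(), max_k = 100000L) {
  stopifnot(inherits(params, "model_params"))
  if (probability_level <= 0 || probability_level > 1)
    abort_validation("'probability_level' must be in (0, 1]")
  sw <- sweep_rho0(params, grid, max_k)
  hit <- which(sw$p_canonize_false <= probability_level)
  if (!length(hit))
    abort_no_crossing(sprintf(
      "p_canonize(false) never falls to %g on the grid (min %.4g at rho0 = %g)",
      probability_level, min(sw$p_canonize_false),
      sw$rho0[which.min(sw$p_canonize_false)]))
  i <- hit[1L]
  structure(sw$rho0[i],
            grid_step = if (length(grid) > 1) min(diff(grid)) else NA_real_,
            p_at_threshold = sw$p_canonize_false[i])
}

#' Relative publication rate of negative versus positive studies
#'
#' The worked example from registered antidepressant trials: given how many
#' of the positive and negative studies in a registry were published as
#' such, returns the negative-result publication rate as a percentage of the
#' positive-result rate, `100 * (neg_published/neg_total) /
#' (pos_published/pos_total)`.
#'
#' @param pos_published,pos_total positive studies published / registered.
#' @param neg_published,neg_total negative studies published as negative /
#'   registered.
#' @return Percentage (scalar). `published_rate_ratio(37, 38, 3, 24)` is
#'   about 12.8: negative trials published at scarcely more than a tenth of
#'   the positive rate.
#' @export
published_rate_ratio <- function(pos_published, pos_total,
                                 neg_published, neg_total) {
  counts <- c(pos_published, pos_total, neg_published, neg_total)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    abort_validation("all counts must be nonnegative integers")
  if (pos_total <= 0 || neg_total <= 0)
    abort_validation("totals must be positive")
  if (pos_published > pos_total || neg_published > neg_total)
    abort_validation("published counts cannot exceed totals")
  if (pos_published == 0)
    abort_validation("positive publication rate is zero; ratio undefined")
  100 * (neg_published / neg_total) / (pos_published / pos_total)
}
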
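# Closed-form belief algebra: published-outcome probabilities, posteriors,
# log-odds increments, expected drift.

test_that("parameter validation enforces the model's constraints", {
  expect_s3_class(params_strict(), "model_params")
  # uninformative / perverse tests are rejected rather than yielding d1 <= 0
  expect_error(model_params(0.9, 0.4, 1, 0.5, 0.1, 0.9),
               class = "pubcanon_validation_error")
  expect_error(model_params(0.05, 0.2, 1, 0.5, 0.9, 0.1),
               class = "pubcanon_validation_error")
  expect_error(model_params(0.05, 0.2, -0.1, 0.5, 0.1, 0.9),
               class = "pubcanon_validation_error")
  # p-hacking may only inflate the false positive rate
  expect_error(model_params(0.2, 0.2, 1, 0.5, 0.1, 0.9, alpha_act = 0.1),
               class = "pubcanon_validation_error")
  # alpha_act must itself leave the test informative
  expect_error(model_params(0.05, 0.2, 1, 0.5, 0.1, 0.9, alpha_act = 0.85),
               class = "pubcanon_validation_error")
  # rho0 > rho1 is allowed but flagged as the grey regime
  expect_true(model_params(0.05, 0.2, 1.5, 0.5, 0.1, 0.9)$grey)
  expect_false(params_strict()$grey)
})

test_that("published-positive probabilities follow the bias-weighted form", {
  base <- function(...) model_params(..., q0 = 0.5, tau0 = 0.1, tau1 = 0.9)
  # no publication bias: omega reduces to the raw outcome rates
  expect_equal(omega_true(base(0.05, beta = 0.2, rho0 = 1)), 0.8)
  expect_equal(omega_false(base(0.05, beta = 0.2, rho0 = 1)), 0.05)
  expect_equal(omega_true(base(0.05, beta = 0.5, rho0 = 1)), 0.5)
  # biased: 0.6 / (0.6 + 0.4 * 0.1) and 0.2 / (0.2 + 0.8 * 0.1)
  expect_equal(omega_true(base(0.2, beta = 0.4, rho0 = 0.1)), 0.9375)
  expect_equal(omega_false(base(0.2, beta = 0.4, rho0 = 0.1)), 0.2 / 0.28,
               tolerance = 1e-6)
  # p-hacked variant runs on the actual rate; no bias -> alpha_act
  expect_equal(omega_false(base(0.05, beta = 0.2, rho0 = 1, alpha_act = 0.25)),
               0.25)
  # omega_true > omega_false whenever published evidence is informative
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1, 0.01, 0.4); b <- runif(1, 0.05, 1 - a - 0.05)
    aact <- runif(1, a, 1 - b - 1e-3)
    p <- base(a, beta = b, rho0 = runif(1, 0, 2), alpha_act = aact)
    expect_gt(omega_true(p), omega_false(p))
  }
})

test_that("log-odds increments use the nominal rates and have the right signs", {
  st <- log_odds_steps(params_strict(0.05, 0.2))
  expect_equal(st$d1, log(16))
  expect_equal(st$d0, log(0.2 / 0.95))
  # symmetric test: one negative exactly cancels one positive
  st_sym <- log_odds_steps(model_params(0.2, 0.2, 1, 0.5, 0.1, 0.9))
  expect_equal(st_sym$d0, -st_sym$d1)
  expect_gt(log_odds_steps(model_params(0.2, 0.4, 1, 0.5, 0.1, 0.9))$d1, 0)
  # p-hacking leaves the increments at the nominal alpha
  ph <- model_params(0.05, 0.2, 1, 0.5, 0.1, 0.9, alpha_act = 0.25)
  expect_equal(unclass(log_odds_steps(ph))[c("d1", "d0")],
               unclass(st)[c("d1", "d0")])
})

test_that("naive posterior matches the direct product form and the prior", {
  p <- model_params(0.2, 0.4, rho0 = 1, q0 = 0.1, tau0 = 0.01, tau1 = 0.99)
  expect_equal(naive_posterior(p, 0, 0), 0.1)
  expect_equal(naive_posterior(p, 1, 1), 0.25)
  # alpha = beta: a positive and a negative cancel back to the prior
  psym <- model_params(0.3, 0.3, 1, q0 = 0.37, tau0 = 0.01, tau1 = 0.99)
  expect_equal(naive_posterior(psym, 2, 1), 0.37)
  # log-odds evaluation agrees with the product form over a lattice sweep
  for (k in c(1, 5, 20, 100, 200)) {
    y <- 0:k
    expect_equal(naive_posterior(p, k, y),
                 naive_posterior_product(p, k, y), tolerance = 1e-10)
  }
  expect_error(naive_posterior(p, 2, 3), class = "pubcanon_validation_error")
})

test_that("naive posterior is monotone in y and in k", {
  p <- params_weak(0.1, 0.3, rho0 = 0.4)
  for (k in c(3, 10)) {             # deep lattices saturate double precision
    q <- naive_posterior(p, k, 0:k)
    expect_true(all(diff(q) > 0))   # more positives, more belief
  }
  for (y in c(0, 2, 5)) {
    q <- naive_posterior(p, y + 0:20, y)
    expect_true(all(diff(q) < 0))   # more negatives at fixed y, less belief
  }
})

test_that("bias-aware posterior generalizes the naive one", {
  p <- model_params(0.2, 0.4, rho0 = 0.1, q0 = 0.1, tau0 = 0.01, tau1 = 0.99)
  expect_equal(informed_posterior(p, 0, 0), 0.1)
  expect_equal(informed_posterior(p, 1, 1), 0.09375 / (0.09375 + 0.642857142857),
               tolerance = 1e-6)
  # rho0 = rho1: knowing the (absent) bias changes nothing
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, 0.01, 0.3); b <- runif(1, 0.05, 0.5)
    pp <- model_params(a, b, rho0 = 1, q0 = runif(1, 0.05, 0.95),
                       tau0 = 0.01, tau1 = 0.99)
    k <- sample(0:30, 1); y <- sample(0:k, 1)
    expect_equal(informed_posterior(pp, k, y), naive_posterior(pp, k, y),
                 tolerance = 1e-12)
  }
  # rho0 = 0: only positives can be published and they carry less weight
  p0 <- model_params(0.2, 0.4, rho0 = 0, q0 = 0.3, tau0 = 0.01, tau1 = 0.99)
  expect_equal(informed_posterior(p0, 0, 0), 0.3)
  expect_true(is.finite(informed_posterior(p0, 5, 5)))
  # the informed reader discounts a run of positives more than the naive one
  expect_lt(informed_posterior(p, 5, 5), naive_posterior(p, 5, 5))
})

test_that("belief states tie the lattice, belief and log odds together", {
  p <- params_weak(0.1, 0.3, rho0 = 0.4)
  st <- log_odds_steps(p)
  bs <- belief_state(p, 7, 4)
  expect_equal(bs$log_odds,
               qlogis(p$q0) + 4 * st$d1 + 3 * st$d0)
  expect_equal(bs$belief, plogis(bs$log_odds), tolerance = 1e-12)
  expect_error(belief_state(p, 3, 4), class = "pubcanon_validation_error")
})

test_that("expected drift matches the omega-weighted increments", {
  p <- model_params(0.2, 0.4, rho0 = 0.1, q0 = 0.5, tau0 = 0.1, tau1 = 0.9)
  expect_equal(expected_drift(p, "false"),
               (0.2 / 0.28) * log(3) + (0.08 / 0.28) * log(0.5),
               tolerance = 1e-10)
  expect_equal(expected_drift(p, "false"), 0.58668, tolerance = 1e-4)
  # without publication bias the drift has the truthful sign (Gibbs)
  set.seed(11)
  for (i in 1:30) {
    a <- runif(1, 0.01, 0.4); b <- runif(1, 0.05, 1 - a - 0.05)
    pu <- model_params(a, b, rho0 = 1, q0 = 0.5, tau0 = 0.1, tau1 = 0.9)
    expect_lt(expected_drift(pu, "false"), 0)
    expect_gt(expected_drift(pu, "true"), 0)
  }
})

test_that("false-claim drift decreases in rho0 and vanishes at the closed-form root", {
  p <- params_strict(0.05, 0.2)
  grid <- seq(0.01, 1, by = 0.01)
  drifts <- vapply(grid, function(r)
    expected_drift(update_params(p, rho0 = r), "false"), 0)
  expect_true(all(diff(drifts) < 0))
  root <- drift_zero_rho0(p, "false")
  expect_equal(root, 0.09365, tolerance = 1e-4 / 0.09365)
  expect_lt(abs(expected_drift(update_params(p, rho0 = root), "false")), 1e-10)
  root2 <- drift_zero_rho0(params_strict(0.05, 0.4), "false")
  expect_equal(root2, 0.151, tolerance = 1e-2)
  # true claims drift upward everywhere on (0, 1]: no root to find
  expect_error(drift_zero_rho0(p, "true"), class = "pubcanon_no_crossing")
})
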
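# Exact first-passage engine on the publication lattice.

test_that("state partitions split the lattice by belief thresholds", {
  # prior inside the undecided band: the single k = 0 state is interior
  p0 <- params_weak()
  part0 <- partition_states(p0, 0)
  expect_equal(part0$interior, 0L)
  expect_length(part0$canon, 0)
  expect_length(part0$reject, 0)
  # wide standards keep both one-publication states interior
  p1 <- model_params(0.2, 0.4, 1, q0 = 0.5, tau0 = 0.1, tau1 = 0.9)
  part1 <- partition_states(p1, 1)
  expect_equal(part1$interior, c(0L, 1L))     # beliefs 1/3 and 3/4
  # tight standards absorb both: 0.75 > 0.6 canonized, 1/3 < 0.4 rejected
  p2 <- params_one_step()
  part2 <- partition_states(p2, 1)
  expect_equal(part2$canon, 1L)
  expect_equal(part2$reject, 0L)
  expect_length(part2$interior, 0)
  # the three sets always partition 0..k
  for (k in c(0, 3, 17)) {
    pp <- partition_states(params_strict(), k)
    expect_setequal(c(pp$canon, pp$interior, pp$reject), 0:k)
  }
})

test_that("forward step conserves mass and honours the interior contract", {
  p <- params_weak(0.2, 0.4, rho0 = 0.5)
  w <- omega_false(p)
  out <- forward_step(c(`0` = 1), 0, p, "false")
  expect_equal(unname(out[c("1", "0")]), c(w, 1 - w))
  # several interior states: total mass conserved
  mass <- c(`0` = 0.2, `1` = 0.5, `2` = 0.3)
  out2 <- forward_step(mass, 2, p, "false")
  expect_equal(sum(out2), 1)
  # mass parked outside the interior is a contract violation
  p_tight <- params_one_step()
  expect_error(forward_step(c(`1` = 1), 1, p_tight, "false"),
               class = "pubcanon_validation_error")
  # a belief-linked policy with baseline 1 degenerates to constant rho0 = 1
  p_unbiased <- model_params(0.2, 0.4, 1, q0 = 0.5, tau0 = 0.1, tau1 = 0.9)
  expect_equal(
    forward_step(mass, 2, p_unbiased, "false",
                 publication_policy("belief_linked", 1)),
    forward_step(mass, 2, p_unbiased, "false"))
})

test_that("one-publication absorption is a single Bernoulli trial", {
  res <- absorption_probabilities(params_one_step(), "false")
  expect_equal(res$p_canonize, 0.2, tolerance = 1e-12)
  expect_equal(res$p_reject, 0.8, tolerance = 1e-12)
  expect_equal(res$k_star, 1L)
  expect_equal(as.numeric(expected_publications(res)), 1.0)
  res_t <- absorption_probabilities(params_one_step(), "true")
  expect_equal(res_t$p_canonize, 0.6, tolerance = 1e-12)  # omega_true
})

test_that("symmetric parameter sets reproduce gambler's-ruin arithmetic", {
  p <- params_ruin()
  res <- absorption_probabilities(p, "false")
  expect_equal(res$p_canonize, 0.1, tolerance = p$epsilon + 1e-10)
  expect_equal(ruin_canonize_prob(p), 0.1)   # the oracle itself
  expect_gte(as.numeric(expected_publications(res)), 2)
  # a second symmetric set, farther boundaries
  p2 <- model_params(0.3, 0.3, 1, q0 = 0.5, tau0 = 0.05, tau1 = 0.95)
  res2 <- absorption_probabilities(p2, "false")
  expect_equal(res2$p_canonize, ruin_canonize_prob(p2),
               tolerance = p2$epsilon + 1e-10)
  # and the conjugate claim: true claims mirror with p -> 1 - p
  res2t <- absorption_probabilities(p2, "true")
  expect_equal(res2t$p_reject, ruin_canonize_prob(p2),
               tolerance = p2$epsilon + 1e-10)
})

test_that("degenerate and immediate-absorption cases are handled", {
  # rho0 = 0: no negative ever published, belief can only rise
  p0 <- model_params(0.05, 0.2, rho0 = 0, q0 = 0.5, tau0 = 0.1, tau1 = 0.9)
  res0 <- absorption_probabilities(p0, "false")
  expect_equal(res0$p_canonize, 1, tolerance = p0$epsilon)
  expect_equal(res0$p_reject, 0)
  # prior already beyond a standard: absorbed before any publication
  hi <- model_params(0.05, 0.2, 1, q0 = 0.95, tau0 = 0.1, tau1 = 0.9)
  res_hi <- absorption_probabilities(hi, "false")
  expect_equal(res_hi$p_canonize, 1)
  expect_equal(res_hi$k_star, 0L)
  expect_equal(as.numeric(expected_publications(res_hi)), 0)
  lo <- model_params(0.05, 0.2, 1, q0 = 0.05, tau0 = 0.1, tau1 = 0.9)
  expect_equal(absorption_probabilities(lo, "true")$p_reject, 1)
  # refusing to converge within the cap is a diagnosable error
  expect_error(
    absorption_probabilities(params_strict(0.25, 0.2, rho0 = 0.35), "false",
                             max_k = 10L),
    class = "pubcanon_no_convergence")
})

test_that("absorption results conserve probability and respect epsilon", {
  set.seed(5)
  for (i in 1:12) {
    a <- runif(1, 0.02, 0.3); b <- runif(1, 0.1, 0.5)
    p <- model_params(a, b, rho0 = runif(1, 0.05, 1),
                      q0 = runif(1, 0.2, 0.8), tau0 = 0.05, tau1 = 0.95)
    for (tr in c("false", "true")) {
      res <- absorption_probabilities(p, tr)
      expect_equal(res$p_canonize + res$p_reject + res$p_undecided, 1,
                   tolerance = 1e-12)
      expect_lte(res$p_undecided, p$epsilon)
      expect_true(all(res$phi_canonize >= 0) && all(res$phi_reject >= 0))
      expect_equal(sum(res$phi_canonize), res$p_canonize)
    }
  }
})

test_that("canonizing a false claim gets harder as negatives are published more", {
  grid <- seq(0.05, 1, by = 0.05)
  for (a in c(0.05, 0.25)) for (b in c(0.2, 0.4)) {
    for (taus in list(c(0.1, 0.9), c(0.001, 0.999))) {
      p <- model_params(a, b, rho0 = 1, q0 = 0.5,
                        tau0 = taus[1], tau1 = taus[2])
      pc <- vapply(grid, function(r)
        absorption_probabilities(update_params(p, rho0 = r), "false")$p_canonize,
        0)
      expect_true(all(diff(pc) <= 1e-9),
                  label = sprintf("nonincreasing at alpha=%g beta=%g tau0=%g",
                                  a, b, taus[1]))
    }
  }
})

test_that("true claims survive strict standards at any negative publication rate", {
  p <- params_strict(0.05, 0.2)
  for (r in seq(0.1, 1, by = 0.1)) {
    res <- absorption_probabilities(update_params(p, rho0 = r), "true")
    expect_gt(res$p_canonize, 0.99)
    expect_lte(res$p_undecided, 1e-4)
  }
})

test_that("stricter standards can backfire when false positives are common", {
  weak <- model_params(0.25, 0.2, rho0 = 0.1, q0 = 0.5,
                       tau0 = 0.1, tau1 = 0.9)
  strict <- update_params(weak, tau0 = 0.001, tau1 = 0.999)
  expect_gt(absorption_probabilities(strict, "false")$p_canonize,
            absorption_probabilities(weak, "false")$p_canonize)
})

test_that("p-hacking keeps false canonization alive even without publication bias", {
  ph <- model_params(0.05, 0.2, rho0 = 1, q0 = 0.5,
                     tau0 = 0.001, tau1 = 0.999, alpha_act = 0.25)
  base <- update_params(ph, alpha_act = 0.05)
  p_ph <- absorption_probabilities(ph, "false")$p_canonize
  expect_gt(p_ph, 0)
  expect_gt(p_ph, absorption_probabilities(base, "false")$p_canonize)
})

test_that("belief-linked negative publication weakly beats the constant policy", {
  for (a in c(0.05, 0.25)) for (rb in c(0.05, 0.2, 0.6, 1)) {
    p <- model_params(a, 0.4, rho0 = rb, q0 = 0.5, tau0 = 0.001, tau1 = 0.999)
    pc_const <- absorption_probabilities(p, "false")$p_canonize
    pc_dyn <- absorption_probabilities(
      p, "false", publication_policy("belief_linked", rb))$p_canonize
    expect_lte(pc_dyn, pc_const + 1e-9)
  }
})

test_that("stepwise conservation holds while iterating the recursion manually", {
  # absorbed-so-far plus interior mass stays 1 at every publication count
  p <- params_weak(0.1, 0.3, rho0 = 0.3)
  mass <- c(`0` = 1)
  absorbed <- 0
  for (k in 0:25) {
    out <- forward_step(mass, k, p, "false")
    part <- partition_states(p, k + 1)
    y <- as.integer(names(out))
    inside <- y %in% part$interior
    absorbed <- absorbed + sum(out[!inside])
    mass <- out[inside]
    expect_equal(absorbed + sum(mass), 1, tolerance = 1e-12)
  }
})
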
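# Shared parameter sets and small independent oracles.

# Unbiased one-step set: with tau = (0.4, 0.6) the very first publication
# crosses a standard, so absorption probabilities are a single Bernoulli.
params_one_step <- function() {
  model_params(alpha = 0.2, beta = 0.4, rho0 = 1, q0 = 0.5,
               tau0 = 0.4, tau1 = 0.6)
}

# Symmetric set (alpha = beta) whose belief walk is a +/-1 random walk on
# the d1 lattice: exact gambler's-ruin arithmetic applies.
params_ruin <- function() {
  model_params(alpha = 0.25, beta = 0.25, rho0 = 1, q0 = 0.5,
               tau0 = 0.11, tau1 = 0.89)
}

params_strict <- function(alpha = 0.05, beta = 0.2, rho0 = 0.5) {
  model_params(alpha, beta, rho0 = rho0, q0 = 0.5,
               tau0 = 0.001, tau1 = 0.999)
}

params_weak <- function(alpha = 0.05, beta = 0.2, rho0 = 0.5) {
  model_params(alpha, beta, rho0 = rho0, q0 = 0.5, tau0 = 0.1, tau1 = 0.9)
}

# Independent gambler's-ruin oracle for symmetric parameter sets
# (alpha = beta, rho0 = rho1, q0 = 0.5, tau1 = 1 - tau0): belief moves +/- d1
# per publication, so absorption is a biased +/-1 walk between integer
# boundaries. Returns the exact probability of hitting the upper boundary.
ruin_canonize_prob <- function(params) {
  stopifnot(params$alpha == params$beta, params$rho0 == params$rho1,
            params$q0 == 0.5, isTRUE(all.equal(params$tau1, 1 - params$tau0)))
  d1 <- log((1 - params$beta) / params$alpha)
  hi <- stats::qlogis(params$tau1)
  n_up <- floor(hi / d1) + 1L       # steps strictly beyond the standard
  p <- params$alpha                  # published-positive prob for false claim
  r <- (1 - p) / p
  z <- n_up                          # start midway between the boundaries
  N <- 2L * n_up
  (1 - r^z) / (1 - r^N)
}

# Eq-as-written oracle for the naive posterior: direct products of the
# outcome likelihoods, usable while beta^k does not underflow.
naive_posterior_product <- function(params, k, y) {
  a <- params$alpha; b <- params$beta; q0 <- params$q0
  num <- (1 - b)^y * b^(k - y) * q0
  den <- num + a^y * (1 - a)^(k - y) * (1 - q0)
  num / den
}
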
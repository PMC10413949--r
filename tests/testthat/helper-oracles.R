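# Independent oracles used across the test files. These deliberately avoid
# the package's own solver/fitting code paths.

# Closed-form relaxation of the linear two-pool exchange with constant
# compartments and a frozen slow reservoir, in chemical-mass units:
#   dm_f/dt = k1 f_w (A' - m_f) - k2 m_f,  A' = m_total - m_slow
# => m_f(t) = m_eq + (m_f0 - m_eq) exp(-(k2 + k1 f_w) t),
#    m_eq = k1 f_w A' / (k1 f_w + k2)
closed_form_fast_mass <- function(t, m_f0, m_slow, m_total, k1, k2, f_w) {
  a_prime <- m_total - m_slow
  rate <- k2 + k1 * f_w
  m_eq <- k1 * f_w * a_prime / rate
  m_eq + (m_f0 - m_eq) * exp(-rate * t)
}

# Brute-force OLS by iterative grid refinement (no lm()).
grid_ols <- function(x, y, rounds = 6, width = 5, n_grid = 41) {
  s0 <- (y[length(y)] - y[1]) / (x[length(x)] - x[1])
  i0 <- mean(y) - s0 * mean(x)
  centre <- c(s0, i0)
  for (r in seq_len(rounds)) {
    ss <- seq(centre[1] - width, centre[1] + width, length.out = n_grid)
    ii <- seq(centre[2] - width, centre[2] + width, length.out = n_grid)
    sse <- outer(ss, ii, Vectorize(function(s, i) sum((y - s * x - i)^2)))
    best <- arrayInd(which.min(sse), dim(sse))
    centre <- c(ss[best[1]], ii[best[2]])
    width <- width / 8
  }
  list(slope = centre[1], intercept = centre[2])
}

# Forward closed-system mass balance: sampler reading implied by known
# partition coefficients (the generating direction of the estimators).
forward_pom_reading <- function(c_w, k_pom, pom_conc, k_micelle = 0,
                                micelle_conc = 0, k_oil = 0, oil_conc = 0) {
  c_init <- c_w * (1 + k_pom * pom_conc + k_micelle * micelle_conc +
                     k_oil * oil_conc)
  list(c_init = c_init, c_pom_star = k_pom * c_w)
}

# Default kinetic parameter set with plausible mid-range partition
# coefficients for quick construction in tests.
test_kp <- function(k1 = 9298, k2 = 1, log_kow = 6.71) {
  kinetic_params(
    k1 = k1, k2 = k2,
    k_micelle = 10^(0.99 * log_kow + 0.61),
    k_oil = 10^(0.85 * log_kow + 2.21),
    k_pom = 10^(0.85 * log_kow + 0.30))
}
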
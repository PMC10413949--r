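test_that("sampler inversion recovers the freely dissolved concentration", {
  expect_equal(pom_to_water(0, 1e6), 0)
  expect_equal(pom_to_water(1e6, 1e6), 1)
  expect_equal(pom_to_water(5.0e5, 2.0e5), 2.5)
  expect_error(pom_to_water(1, 0), "> 0")
})

test_that("micelle estimator inverts the forward mass balance exactly", {
  # forward-generated instance: C_w = 0.01, K_micelle = 1e7
  fw <- forward_pom_reading(c_w = 0.01, k_pom = 1e6, pom_conc = 1.375e-3,
                            k_micelle = 1e7, micelle_conc = 5.7e-3)
  expect_equal(fw$c_init, 583.76)
  exp1 <- partition_experiment(c_init = fw$c_init,
                               c_pom_star = fw$c_pom_star, k_pom = 1e6,
                               pom_conc = 1.375e-3, micelle_conc = 5.7e-3)
  est <- estimate_k_micelle(exp1)
  expect_equal(est$k_micelle, 1e7, tolerance = 1e-12)
  expect_equal(est$flag, "ok")

  # no micelle sorption: c_init accounted for by water + POM alone
  exp0 <- partition_experiment(c_init = 0.01 * (1 + 1e6 * 1.375e-3),
                               c_pom_star = 1e4, k_pom = 1e6,
                               pom_conc = 1.375e-3, micelle_conc = 5.7e-3)
  expect_equal(estimate_k_micelle(exp0)$k_micelle, 0, tolerance = 1e-9)

  # doubling micelle_conc at fixed readings halves the estimate
  exp2 <- exp1; exp2$micelle_conc <- 2 * exp1$micelle_conc
  expect_equal(estimate_k_micelle(exp2)$k_micelle,
               est$k_micelle / 2, tolerance = 1e-12)
})

test_that("oil estimator inverts its forward balance and degenerates cleanly", {
  for (oil_conc in c(1.3e-3, 12.6e-3)) {
    fw <- forward_pom_reading(c_w = 0.005, k_pom = 8e5, pom_conc = 1.375e-2,
                              k_micelle = 2e6, micelle_conc = 5.7e-3,
                              k_oil = 5e7, oil_conc = oil_conc)
    exp1 <- partition_experiment(c_init = fw$c_init,
                                 c_pom_star = fw$c_pom_star, k_pom = 8e5,
                                 pom_conc = 1.375e-2,
                                 micelle_conc = 5.7e-3, oil_conc = oil_conc)
    est <- estimate_k_oil(exp1, k_micelle = 2e6)
    # a true constant is invariant to the phase concentration used
    expect_equal(est$k_oil, 5e7, tolerance = 1e-10)
  }
  # micelle-free two-phase balance
  fw <- forward_pom_reading(c_w = 0.02, k_pom = 1e5, pom_conc = 1e-2,
                            k_oil = 1e6, oil_conc = 6.3e-3)
  exp2 <- partition_experiment(c_init = fw$c_init,
                               c_pom_star = fw$c_pom_star, k_pom = 1e5,
                               pom_conc = 1e-2, micelle_conc = 0,
                               oil_conc = 6.3e-3)
  expect_equal(estimate_k_oil(exp2, k_micelle = 0)$k_oil, 1e6,
               tolerance = 1e-10)
})

test_that("negative estimates are flagged, not clipped", {
  # noise pushes the sampler reading above what the spike supports
  exp1 <- partition_experiment(c_init = 1, c_pom_star = 1e4, k_pom = 1e6,
                               pom_conc = 1.375e-3, micelle_conc = 5.7e-3)
  est <- estimate_k_micelle(exp1)
  expect_true(est$k_micelle < 0)
  expect_equal(est$flag, "negative")
})

test_that("round-trip inversion and scale invariance hold across random draws", {
  set.seed(42)
  for (i in 1:25) {
    c_w <- 10^stats::runif(1, -4, 0)
    k_mic <- 10^stats::runif(1, 5, 8)
    k_oil <- 10^stats::runif(1, 6, 9)
    k_pom <- 10^stats::runif(1, 4, 7)
    mic <- stats::runif(1, 1e-3, 7e-2)
    oil <- stats::runif(1, 1e-3, 2e-2)
    pom <- stats::runif(1, 1e-3, 2e-2)
    fw <- forward_pom_reading(c_w, k_pom, pom, k_mic, mic, k_oil, oil)
    exp1 <- partition_experiment(c_init = fw$c_init,
                                 c_pom_star = fw$c_pom_star, k_pom = k_pom,
                                 pom_conc = pom, micelle_conc = mic,
                                 oil_conc = oil)
    expect_equal(estimate_k_oil(exp1, k_mic)$k_oil, k_oil,
                 tolerance = 1e-10)
    # same phase masses in a rescaled system volume: every per-litre
    # concentration (including the spike and the equilibrium C_w) changes,
    # but the recovered constant does not
    s <- stats::runif(1, 0.2, 5)
    c_w_s <- (fw$c_init * s) / (1 + k_pom * pom * s + k_mic * mic * s +
                                  k_oil * oil * s)
    exp_s <- partition_experiment(c_init = fw$c_init * s,
                                  c_pom_star = k_pom * c_w_s,
                                  k_pom = k_pom, pom_conc = pom * s,
                                  micelle_conc = mic * s,
                                  oil_conc = oil * s)
    expect_equal(estimate_k_oil(exp_s, k_mic)$k_oil, k_oil,
                 tolerance = 1e-10)
  }
})

test_that("log-linear OLS matches exact affine data and a grid-search oracle", {
  x <- seq(5.24, 8.18, length.out = 10)
  y <- 0.99 * x + 0.61
  rel <- fit_loglinear(x, y)
  expect_equal(rel$slope, 0.99, tolerance = 1e-10)
  expect_equal(rel$intercept, 0.61, tolerance = 1e-10)
  expect_equal(rel$r2, 1)
  expect_equal(rel$n, 10)

  # two points: perfect interpolation
  rel2 <- fit_loglinear(c(5, 8), c(1, 4))
  expect_equal(rel2$slope, 1, tolerance = 1e-12)
  expect_equal(rel2$r2, 1)

  # noisy data: agrees with brute-force grid refinement
  set.seed(7)
  yn <- 0.85 * x + 2.21 + stats::rnorm(10, sd = 0.3)
  rel3 <- fit_loglinear(x, yn)
  oracle <- grid_ols(x, yn)
  expect_equal(rel3$slope, oracle$slope, tolerance = 1e-4)
  expect_equal(rel3$intercept, oracle$intercept, tolerance = 1e-4)
  expect_true(rel3$se_slope > 0)

  expect_error(fit_loglinear(rep(6, 4), 1:4), "zero variance")
})

test_that("grouped fits return one relation per level plus the pooled fit", {
  x <- rep(seq(5.5, 8, length.out = 8), 2)
  g <- rep(c("lo", "hi"), each = 8)
  y <- ifelse(g == "lo", 1.0 * x + 0.5, 1.0 * x + 0.9)
  fits <- fit_loglinear_groups(x, y, g)
  expect_named(fits, c("hi", "lo", "pooled"))
  expect_equal(fits$lo$intercept, 0.5, tolerance = 1e-10)
  expect_equal(fits$hi$intercept, 0.9, tolerance = 1e-10)
  expect_equal(fits$pooled$intercept, 0.7, tolerance = 1e-10)
})
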
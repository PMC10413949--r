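no_digestion <- function(...) {
  digestion_params(ffa_max = 0, k_ffa = 1, ...)
}

test_that("freely dissolved pool fraction follows the partition balance", {
  kp0 <- kinetic_params(k_micelle = 0, k_oil = 0, k_pom = 0)
  expect_equal(water_fraction(kp0, 5.7e-3, 8.76e-2, 1e-3), 1)
  kp1 <- kinetic_params(k_micelle = 1e5, k_oil = 0, k_pom = 0)
  expect_equal(water_fraction(kp1, 5.7e-3, 0), 1 / 571, tolerance = 1e-12)
  # doubling every K while halving every phase concentration is a no-op
  kp2 <- kinetic_params(k_micelle = 2e5, k_oil = 2e7, k_pom = 2e6)
  kp3 <- kinetic_params(k_micelle = 1e5, k_oil = 1e7, k_pom = 1e6)
  expect_equal(water_fraction(kp2, 2.85e-3, 4e-2, 5e-4),
               water_fraction(kp3, 5.7e-3, 8e-2, 1e-3))
})

test_that("total-anchored initialisation distributes mass by phase affinity", {
  # symmetric system: equal K and equal phase masses -> equal chemical in
  # micelle, oil and LDPE, each K*conc times the water share
  sys <- gut_system(v_w = 1, ldpe_conc0 = 1e-2, n_strips0 = 10,
                    removal_times = numeric(0),
                    digestion = no_digestion(micelle0 = 1e-2, oil0 = 1e-2))
  kp <- kinetic_params(k1 = 1, k2 = 1, f1 = 1, k_micelle = 1e4,
                       k_oil = 1e4, k_pom = 0, k_p = 1e4)
  s0 <- initialize_state(sys, kp, c_total = 300)
  m_ldpe <- s0$m_ldpe_fast + s0$m_ldpe_slow
  share <- 1e4 * 1e-2            # K * conc = 100 per sorbing phase
  expect_equal(s0$m_total, 300)
  expect_equal(m_ldpe, 300 * share / (1 + 3 * share), tolerance = 1e-12)
  expect_equal(s0$m_pool, 300 * (1 + 2 * share) / (1 + 3 * share),
               tolerance = 1e-12)
  # f1 = 1 puts everything in the fast reservoir
  expect_equal(s0$m_ldpe_slow, 0)
})

test_that("POM-anchored initialisation substitutes the sampler reading", {
  sys <- gut_system(digestion = no_digestion(), removal_times = numeric(0))
  kp <- kinetic_params(k1 = 1e4, k2 = 1, f1 = 0.5, k_micelle = 1e6,
                       k_oil = 1e7, k_pom = 1e6)
  s0 <- initialize_state(sys, kp, c_pom_star_day28 = 1e6)
  c_w <- 1    # 1e6 / 1e6 ug/L
  mass_mic <- sys$digestion$micelle0 * sys$v_w
  expect_equal(s0$m_pool - kp$k_oil * c_w * sys$digestion$oil0 * sys$v_w -
                 c_w * sys$v_w / sys$dilution_factor,
               kp$k_micelle * mass_mic * c_w, tolerance = 1e-12)
  # fast:slow split follows f1
  expect_equal(s0$m_ldpe_fast, s0$m_ldpe_slow)
  expect_error(initialize_state(sys, kp), "exactly one")
  expect_error(initialize_state(sys, kp, c_pom_star_day28 = 1, c_total = 1),
               "exactly one")
})

test_that("equilibrium start with no digestion is a fixed point", {
  sys <- gut_system(digestion = no_digestion(), removal_times = numeric(0))
  kp <- test_kp()
  kp$k_p <- derive_kp(kp$k1, kp$k2, sys$ldpe_conc0, kp$f1)
  s0 <- initialize_state(sys, kp, c_total = 80)
  traj <- simulate_exchange(sys, kp, s0, c(0, 2, 10, 24, 72))
  rel_drift <- abs(traj$c_ldpe_star / traj$c_ldpe_star[1] - 1)
  expect_true(all(rel_drift < 1e-8))
  expect_true(all(abs(traj$c_w / traj$c_w[1] - 1) < 1e-8))
  expect_equal(fold_increase(traj), 1, tolerance = 1e-8)
})

test_that("solver matches the closed-form linear relaxation oracle", {
  sys <- gut_system(digestion = no_digestion(), removal_times = numeric(0))
  tt <- c(0, 0.5, 1, 2, 4, 8, 16, 32, 72)
  for (pars in list(c(k1 = 1e3, k2 = 0.5), c(k1 = 1e6, k2 = 4.36),
                    c(k1 = 138, k2 = 0.087))) {
    kp <- test_kp(k1 = pars[["k1"]], k2 = pars[["k2"]])
    kp$k_p <- derive_kp(kp$k1, kp$k2, sys$ldpe_conc0, kp$f1)
    s0 <- initialize_state(sys, kp, c_total = 50)
    # start the fast reservoir off equilibrium
    s0$m_pool <- s0$m_pool + 0.9 * s0$m_ldpe_fast
    s0$m_ldpe_fast <- 0.1 * s0$m_ldpe_fast
    traj <- simulate_exchange(sys, kp, s0, tt)
    f_w <- water_fraction(kp, sys$digestion$micelle0, sys$digestion$oil0)
    oracle <- closed_form_fast_mass(tt, s0$m_ldpe_fast, s0$m_ldpe_slow,
                                    s0$m_total, kp$k1, kp$k2, f_w)
    expect_equal(traj$m_ldpe_fast, oracle, tolerance = 1e-6)
  }
})

test_that("mass is conserved along trajectories with removal events", {
  sys <- gut_system()   # digestion on, removals at 0..72 h
  kp <- test_kp()
  kp$k_p <- derive_kp(kp$k1, kp$k2, sys$ldpe_conc0, kp$f1)
  s0 <- initialize_state(sys, kp, c_total = 124)
  s0$m_pool <- s0$m_pool + 0.9 * (s0$m_ldpe_fast + s0$m_ldpe_slow)
  s0$m_ldpe_fast <- 0.1 * s0$m_ldpe_fast
  s0$m_ldpe_slow <- 0.1 * s0$m_ldpe_slow
  traj <- simulate_exchange(sys, kp, s0, c(0, 1, 3, 5, 7, 9, 12, 36, 60, 72))
  balance <- traj$m_ldpe_fast + traj$m_ldpe_slow + traj$m_pool +
    traj$m_removed
  expect_true(all(abs(balance / s0$m_total - 1) < 1e-6))
  # the instantaneous-equilibrium pool decomposes exactly
  expect_equal(traj$c_micelle, kp$k_micelle * traj$micelle_conc * traj$c_w)
  expect_equal(traj$c_oil, kp$k_oil * traj$oil_conc * traj$c_w)
  # removal log is consistent with the bookkeeping column
  rem <- attr(traj, "removals")
  expect_equal(sum(rem$chem_removed_ug[rem$t_h < 72]),
               traj$m_removed[nrow(traj)])
})

test_that("strip removal is proportional and solid-basis continuous", {
  sys <- gut_system(digestion = no_digestion(), removal_times = 10,
                    n_strips0 = 10)
  kp <- test_kp()
  kp$k_p <- derive_kp(kp$k1, kp$k2, sys$ldpe_conc0, kp$f1)
  s0 <- initialize_state(sys, kp, c_total = 60)
  eps <- 1e-6
  traj <- simulate_exchange(sys, kp, s0, c(0, 10, 10 + eps, 72))
  # system-basis LDPE concentration drops by the removed share (1/10)
  expect_equal(traj$c_ldpe[3] / traj$c_ldpe[2], 0.9, tolerance = 1e-4)
  # solid-basis concentration is continuous across the event
  expect_equal(traj$c_ldpe_star[3], traj$c_ldpe_star[2], tolerance = 1e-4)
  expect_equal(traj$strips_remaining, c(10, 10, 9, 9))
})

test_that("stored values are independent of the output grid resolution", {
  sys <- gut_system()
  kp <- test_kp()
  kp$k_p <- derive_kp(kp$k1, kp$k2, sys$ldpe_conc0, kp$f1)
  s0 <- initialize_state(sys, kp, c_total = 90)
  s0$m_pool <- s0$m_pool + 0.9 * s0$m_ldpe_fast
  s0$m_ldpe_fast <- 0.1 * s0$m_ldpe_fast
  coarse <- simulate_exchange(sys, kp, s0, c(0, 6, 24, 72))
  fine <- simulate_exchange(sys, kp, s0, sort(unique(c(seq(0, 72, by = 1.5),
                                                       6, 24))))
  idx <- match(coarse$t_h, fine$t_h)
  expect_equal(coarse$c_ldpe_star, fine$c_ldpe_star[idx], tolerance = 1e-6)
  expect_equal(coarse$m_pool, fine$m_pool[idx], tolerance = 1e-6)
})

test_that("increasing k1 never decreases plastic loading", {
  sys <- gut_system(removal_times = numeric(0))
  tt <- c(0, 2, 6, 12, 24, 48, 72)
  # one common starting state for all k1 values
  kp_ref <- test_kp(k1 = 1e2, k2 = 1)
  kp_ref$k_p <- derive_kp(1e4, 1, sys$ldpe_conc0, kp_ref$f1)
  s0 <- initialize_state(sys, kp_ref, c_total = 70)
  s0$m_pool <- s0$m_pool + 0.95 * s0$m_ldpe_fast
  s0$m_ldpe_fast <- 0.05 * s0$m_ldpe_fast
  prev <- NULL
  for (k1 in c(1e2, 1e3, 1e4)) {
    kp <- test_kp(k1 = k1, k2 = 1)
    traj <- simulate_exchange(sys, kp, s0, tt)
    if (!is.null(prev))
      expect_true(all(traj$c_ldpe_star >= prev$c_ldpe_star - 1e-9))
    prev <- traj
  }
})

test_that("fold increase approaches the equilibrium ratio", {
  sys <- gut_system(digestion = no_digestion(), removal_times = numeric(0))
  # all-fast polymer (f1 = 1): the solid-basis ratio is the clean
  # fast-reservoir equilibrium ratio
  kp <- test_kp(k1 = 1e4, k2 = 1)
  kp$f1 <- 1
  kp$k_p <- derive_kp(kp$k1, kp$k2, sys$ldpe_conc0, kp$f1)
  s0 <- initialize_state(sys, kp, c_total = 100)
  # fast reservoir at 10% of its equilibrium
  s0$m_pool <- s0$m_pool + 0.9 * (s0$m_ldpe_fast + s0$m_ldpe_slow)
  s0$m_ldpe_fast <- 0.1 * s0$m_ldpe_fast
  s0$m_ldpe_slow <- 0.1 * s0$m_ldpe_slow
  traj <- simulate_exchange(sys, kp, s0, c(0, seq(100, 2000, by = 100)))
  # pool depletion by LDPE uptake is small here, so the limit is near
  # C_eq / C_0 = 10
  expect_gt(fold_increase(traj), 9)
  expect_lt(fold_increase(traj), 10.5)
  # monotone loading scenario: factor >= 1
  expect_true(all(diff(traj$c_ldpe_star) >= -1e-9))
})

test_that("bioavailability reduction is bounded and zero without exchange", {
  sys <- gut_system(removal_times = numeric(0))
  kp <- test_kp(k1 = 0, k2 = 0)
  kp$k_p <- 1e5
  s0 <- initialize_state(sys, kp, c_total = 50)
  traj <- simulate_exchange(sys, kp, s0, c(0, 24, 72))
  expect_equal(bioavailability_reduction(traj), 0, tolerance = 1e-10)

  kp2 <- test_kp(k1 = 1e4, k2 = 1)
  kp2$k_p <- derive_kp(kp2$k1, kp2$k2, sys$ldpe_conc0, kp2$f1)
  s02 <- initialize_state(sys, kp2, c_total = 50)
  s02$m_pool <- s02$m_pool + 0.9 * s02$m_ldpe_fast
  s02$m_ldpe_fast <- 0.1 * s02$m_ldpe_fast
  traj2 <- simulate_exchange(sys, kp2, s02, c(0, 24, 72))
  red <- bioavailability_reduction(traj2)
  expect_true(red >= -100 && red <= 100)
  expect_gt(red, 0)
})

test_that("long-form trajectory export is faithful", {
  sys <- gut_system(removal_times = numeric(0))
  kp <- test_kp()
  kp$k_p <- derive_kp(kp$k1, kp$k2, sys$ldpe_conc0, kp$f1)
  s0 <- initialize_state(sys, kp, c_total = 40)
  traj <- simulate_exchange(sys, kp, s0, c(0, 24, 72))
  long <- trajectory_long(traj)
  expect_setequal(unique(long$phase), c("water", "micelle", "oil", "pom",
                                        "ldpe"))
  got <- long$value[long$phase == "ldpe" &
                      long$basis == "solid_ug_per_kg"]
  expect_equal(got, traj$c_ldpe_star)
})
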
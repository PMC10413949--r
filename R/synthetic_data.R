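#' Synthetic experiment scenario
#'
#' Defines the study conditions emulated by the synthetic-data generators:
#' a homologous congener series spanning the tested hydrophobicity range,
#' the truth log-linear relations the generators draw partition
#' coefficients and uptake rates from, the digestion kinetics per enzyme
#' level, the sampling/removal schedule and the measurement-noise model.
#' All generation is deterministic given `seed`.
#'
#' Noise is multiplicative lognormal (unit mean, coefficient of variation
#' `noise_cv`) on concentration measurements, which span orders of
#' magnitude, and additive Gaussian (`ffa_noise_sd`, floored at 0) on the
#' FFA series, which does not. The default replicate-level `noise_cv` of
#' 0.1 is a placeholder for the (unreported) replicate variance of such
#' assays.
#'
#' @param n_congeners number of congeners (default 10).
#' @param log_kow_range range of log K_OW (default `c(5.24, 8.18)`).
#' @param truth_relations named list of [log_linear_relation()]s used as
#'   generator truth: `k_micelle`, `k_oil`, `k_pom`, `k1_high`, `k1_low`.
#'   Defaults reproduce pooled regressions measured for PCBs on LDPE in
#'   simulated gut fluid.
#' @param digestion_truth named list of [digestion_params()] per enzyme
#'   level (`high`, `low`).
#' @param k2_truth named numeric, constant desorption-rate truth per
#'   enzyme level (no log-linear trend: desorption correlates only weakly
#'   with hydrophobicity). Defaults 1.0 (high) and 0.15 (low) 1/h, inside
#'   the fitted ranges 0.283-4.36 and 0.087-0.289.
#' @param noise_cv coefficient of variation of lognormal measurement
#'   noise.
#' @param ffa_noise_sd additive noise s.d. on FFA series, uM.
#' @param seed integer seed.
#' @param schedule sampling/removal times, hours.
#' @param n_replicates replicate systems per condition (default 4).
#' @param c_total_range spike totals drawn uniformly, ug/L.
#' @param init_disequilibrium LDPE starting load as a fraction of its
#'   fast-reservoir kinetic equilibrium (default 0.1: plastic near its
#'   measured pre-digestion load, well below the kinetic equilibrium the
#'   digestion phase relaxes toward).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_congeners = 10,
                          log_kow_range = c(5.24, 8.18),
                          truth_relations = list(
                            k_micelle = log_linear_relation(0.99, 0.61, r2 = 0.86),
                            k_oil = log_linear_relation(0.85, 2.21, r2 = 0.84),
                            k_pom = default_k_pom_relation(),
                            k1_high = log_linear_relation(1.04, -3.01, r2 = 0.87),
                            k1_low = log_linear_relation(1.21, -4.28, r2 = 0.96)),
                          digestion_truth = list(
                            high = enzyme_digestion_params("high"),
                            low = enzyme_digestion_params("low")),
                          k2_truth = c(high = 1.0, low = 0.15),
                          noise_cv = 0.1,
                          ffa_noise_sd = 0.2,
                          seed = 1L,
                          schedule = c(0, 2, 4, 6, 8, 10, 24, 48, 72),
                          n_replicates = 4,
                          c_total_range = c(30, 124),
                          init_disequilibrium = 0.1) {
  stopifnot(n_congeners >= 1, noise_cv >= 0, ffa_noise_sd >= 0,
            n_replicates >= 1, init_disequilibrium > 0)
  structure(list(n_congeners = n_congeners, log_kow_range = log_kow_range,
                 truth_relations = truth_relations,
                 digestion_truth = digestion_truth, k2_truth = k2_truth,
                 noise_cv = noise_cv, ffa_noise_sd = ffa_noise_sd,
                 seed = as.integer(seed), schedule = schedule,
                 n_replicates = n_replicates,
                 c_total_range = c_total_range,
                 init_disequilibrium = init_disequilibrium),
            class = "scenario_spec")
}

# unit-mean multiplicative lognormal noise with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic congener series
#'
#' Evenly spaced log K_OW over the scenario range with spike totals drawn
#' uniformly from `c_total_range`; deterministic given the scenario seed.
#'
#' @param spec a [scenario_spec()].
#' @return A [congeners()] table.
#' @export
make_congeners <- function(spec) {
  n <- spec$n_congeners
  lk <- if (n == 1) mean(spec$log_kow_range)
        else seq(spec$log_kow_range[1], spec$log_kow_range[2],
                 length.out = n)
  set.seed(spec$seed)
  ct <- stats::runif(n, spec$c_total_range[1], spec$c_total_range[2])
  congeners(sprintf("C%02d", seq_len(n)), lk, ct)
}

#' Generate a synthetic partition-experiment dataset
#'
#' Forward-computes passive-sampler readings from the closed-system mass
#' balance with truth partition coefficients taken from the scenario's
#' log-linear relations, across the micelle and oil phase-concentration
#' levels of the assay design, in replicate, with lognormal noise on the
#' sampler reading. The micelle experiments contain POM + mixed micelles;
#' the oil experiments also contain the baseline bile-salt micelle pool.
#'
#' @param spec a [scenario_spec()].
#' @param micelle_levels micelle-forming surfactant mass concentrations,
#'   kg/L (defaults: 5.7, 6.9, 11.6, 64.5 g/L).
#' @param oil_levels oil mass concentrations, kg/L (defaults: 1.3, 6.3,
#'   12.6 g/L).
#' @param baseline_micelle bile-salt micelle concentration present in the
#'   oil tubes, kg/L.
#' @param pom_conc POM mass concentration in the tubes, kg/L (default: a
#'   0.11 g strip in 8 mL).
#' @return A `data.frame` with one row per (congener x experiment x level
#'   x replicate): design columns, noisy `c_pom_star`, and the generating
#'   truth `k_micelle_true` / `k_oil_true`.
#' @export
make_partition_dataset <- function(spec,
                                   micelle_levels = c(5.7, 6.9, 11.6, 64.5) / 1e3,
                                   oil_levels = c(1.3, 6.3, 12.6) / 1e3,
                                   baseline_micelle = 5.7e-3,
                                   pom_conc = 0.11e-3 / 8e-3) {
  if (any(c(micelle_levels, oil_levels) <= 0)) stop("levels must be > 0")
  cg <- make_congeners(spec)
  rel <- spec$truth_relations
  design <- rbind(
    expand.grid(i = seq_len(nrow(cg)), level = micelle_levels,
                replicate = seq_len(spec$n_replicates),
                experiment = "micelle", stringsAsFactors = FALSE),
    expand.grid(i = seq_len(nrow(cg)), level = oil_levels,
                replicate = seq_len(spec$n_replicates),
                experiment = "oil", stringsAsFactors = FALSE))
  lk <- cg$log_kow[design$i]
  k_mic <- 10^predict_log_quantity(rel$k_micelle, lk)
  k_oil <- 10^predict_log_quantity(rel$k_oil, lk)
  k_pom <- 10^predict_log_quantity(rel$k_pom, lk)
  is_oil <- design$experiment == "oil"
  micelle_conc <- ifelse(is_oil, baseline_micelle, design$level)
  oil_conc <- ifelse(is_oil, design$level, 0)
  c_init <- cg$c_total[design$i]
  c_w <- c_init / (1 + k_pom * pom_conc + k_mic * micelle_conc +
                     k_oil * oil_conc)
  set.seed(spec$seed + 1L)
  c_pom_star <- k_pom * c_w * rlnorm_cv(nrow(design), spec$noise_cv)
  out <- data.frame(
    id = cg$id[design$i], log_kow = lk, experiment = design$experiment,
    level = design$level, replicate = design$replicate,
    c_init = c_init, c_pom_star = c_pom_star, k_pom = k_pom,
    pom_conc = pom_conc, micelle_conc = micelle_conc, oil_conc = oil_conc,
    k_micelle_true = ifelse(is_oil, NA, k_mic),
    k_oil_true = ifelse(is_oil, k_oil, NA),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic kinetics dataset
#'
#' Runs the digestion-aware exchange model with truth parameters (`k1`
#' from the enzyme-specific log-linear relation, constant `k2` truth,
#' partition coefficients from the scenario relations), samples the
#' solid-basis LDPE concentration at the schedule times with the strip
#' removals applied, and adds lognormal measurement noise per replicate.
#' Also emits a noisy FFA series per replicate from the enzyme's
#' digestion truth. The plastic starts at `init_disequilibrium` times its
#' fast-reservoir kinetic equilibrium, so digestion-phase uptake is
#' observable.
#'
#' @param spec a [scenario_spec()].
#' @param enzyme `"high"` or `"low"`.
#' @param sys optional [gut_system()] template; its digestion parameters
#'   are replaced by the enzyme's truth.
#' @return A list with `observations` (congener x replicate x time,
#'   columns `id`, `log_kow`, `replicate`, `t_h`, `c_ldpe_star` noisy,
#'   `c_ldpe_star_true`), `ffa` (replicate x time, `ffa_uM` noisy),
#'   `truth` (per-congener `k1`, `k2`, `k_p` and shared parameters) and
#'   `sys` (the [gut_system()] used).
#' @export
make_kinetics_dataset <- function(spec, enzyme = c("high", "low"),
                                  sys = NULL) {
  enzyme <- match.arg(enzyme)
  dig <- spec$digestion_truth[[enzyme]]
  if (is.null(sys)) {
    sys <- gut_system(digestion = dig, removal_times = spec$schedule)
  } else {
    sys$digestion <- dig
  }
  cg <- make_congeners(spec)
  rel <- spec$truth_relations
  k1_rel <- rel[[paste0("k1_", enzyme)]]
  k2 <- unname(spec$k2_truth[[enzyme]])
  t_grid <- sort(unique(c(0, spec$schedule)))

  obs_rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(cg))) {
    lk <- cg$log_kow[i]
    kp <- kinetic_params(
      k1 = 10^predict_log_quantity(k1_rel, lk), k2 = k2,
      k_micelle = 10^predict_log_quantity(rel$k_micelle, lk),
      k_oil = 10^predict_log_quantity(rel$k_oil, lk),
      k_pom = 10^predict_log_quantity(rel$k_pom, lk))
    kp$k_p <- derive_kp(kp$k1, kp$k2, sys$ldpe_conc0, kp$f1)

    s0 <- initialize_state(sys, kp, c_total = cg$c_total[i])
    # pull the plastic below its kinetic equilibrium; freed mass returns
    # to the instantaneously equilibrating pool
    m_ldpe <- s0$m_ldpe_fast + s0$m_ldpe_slow
    keep <- spec$init_disequilibrium
    s0$m_pool <- s0$m_pool + (1 - keep) * m_ldpe
    s0$m_ldpe_fast <- keep * s0$m_ldpe_fast
    s0$m_ldpe_slow <- keep * s0$m_ldpe_slow

    traj <- simulate_exchange(sys, kp, s0, t_grid)
    cstar <- traj$c_ldpe_star[match(spec$schedule, traj$t_h)]
    for (r in seq_len(spec$n_replicates)) {
      set.seed(spec$seed + 1000L * i + r)
      noisy <- cstar * rlnorm_cv(length(cstar), spec$noise_cv)
      obs_rows[[length(obs_rows) + 1]] <- data.frame(
        id = cg$id[i], log_kow = lk, replicate = r, t_h = spec$schedule,
        c_ldpe_star = noisy, c_ldpe_star_true = cstar,
        stringsAsFactors = FALSE)
    }
    truth_rows[[i]] <- data.frame(
      id = cg$id[i], log_kow = lk, c_total = cg$c_total[i],
      k1 = kp$k1, k2 = kp$k2, k_p = kp$k_p,
      k_micelle = kp$k_micelle, k_oil = kp$k_oil, k_pom = kp$k_pom,
      stringsAsFactors = FALSE)
  }

  ffa_true <- ffa_at(spec$schedule, dig)
  ffa_rows <- lapply(seq_len(spec$n_replicates), function(r) {
    set.seed(spec$seed + 900000L + r)
    data.frame(replicate = r, t_h = spec$schedule,
               ffa_uM = pmax(ffa_true +
                               stats::rnorm(length(ffa_true),
                                            sd = spec$ffa_noise_sd), 0),
               ffa_uM_true = ffa_true)
  })

  list(observations = do.call(rbind, obs_rows),
       ffa = do.call(rbind, ffa_rows),
       truth = list(per_congener = do.call(rbind, truth_rows),
                    enzyme = enzyme, digestion = dig, f1 = 0.5,
                    init_disequilibrium = spec$init_disequilibrium,
                    seed = spec$seed),
       sys = sys)
}
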
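#' Derive the plastic-water distribution coefficient from rate constants
#'
#' At the fast-reservoir kinetic equilibrium `k1 C_w = k2 C_LDPE,fast`
#' (system-volume basis), so the fast-reservoir solid-basis coefficient is
#' `k1 / (k2 [LDPE])`; scaling by the fast fraction `f1` gives the
#' whole-polymer distribution coefficient
#' `K_P = k1 / (k2 [LDPE] f1)` (L/kg).
#'
#' @param k1 fast uptake rate constant, 1/h; > 0.
#' @param k2 fast desorption rate constant, 1/h; > 0.
#' @param ldpe_conc LDPE mass concentration, kg/L; > 0.
#' @param f1 fast-reservoir fraction, in (0, 1].
#' @return `K_P`, L/kg.
#' @examples
#' derive_kp(1e4, 1, 0.01, 1)
#' @export
derive_kp <- function(k1, k2, ldpe_conc, f1) {
  if (any(c(k1, k2, ldpe_conc, f1) <= 0))
    stop("k1, k2, ldpe_conc and f1 must all be > 0")
  (k1 / k2) / (ldpe_conc * f1)
}

#' Fit the fast uptake and desorption rate constants
#'
#' Nonlinear least squares of the digestion-aware forward model
#' ([simulate_exchange()], with the experiment's strip-removal schedule)
#' against an observed solid-basis LDPE concentration time series. Only
#' `k1` and `k2` are fitted; the partition coefficients, `f1` and `k3` are
#' supplied fixed. The optimisation runs in log10 parameter space with
#' bounds `log10 k1 in [0, 9]` and `log10 k2 in [-4, 2]` (fitted `k1`
#' values span five orders of magnitude across a hydrophobicity series),
#' with a small multi-start sweep if the first start fails.
#'
#' The t = 0 observation sets the LDPE boundary condition; the pool is
#' anchored either by a day-28 sampler reading (`c_pom_star_day28`) or the
#' total concentration (`c_total`), as in [initialize_state()]. A
#' prepared `s0` may be given instead.
#'
#' @param obs `data.frame` with columns `t_h` and `c_ldpe_star` (ug/kg);
#'   at least 4 timepoints including t = 0.
#' @param sys a [gut_system()].
#' @param kp_fixed a [kinetic_params()] with `k_micelle`, `k_oil`,
#'   `k_pom`, `f1`, `k3` set (its `k1`/`k2` are ignored).
#' @param c_pom_star_day28,c_total pool anchors, see
#'   [initialize_state()].
#' @param s0 optional prepared `system_state` (overrides the anchors).
#' @param log10_k1_bounds,log10_k2_bounds fit bounds in log10 space.
#' @param n_starts number of multi-start attempts on failure.
#' @param slow_exchange passed to [simulate_exchange()].
#' @return An object of class `kinetic_fit`: `k1_hat`, `k2_hat` with
#'   standard errors and Wald p-values, `kp_hat` (L/kg, from
#'   [derive_kp()] at the initial LDPE concentration), `convergence`
#'   (`"converged"`, `"bound"`, `"unidentifiable"` or `"failed"`),
#'   per-timepoint `residuals` (ug/kg) and `n_obs`.
#' @export
fit_k1k2 <- function(obs, sys, kp_fixed,
                     c_pom_star_day28 = NULL, c_total = NULL, s0 = NULL,
                     log10_k1_bounds = c(0, 9), log10_k2_bounds = c(-4, 2),
                     n_starts = 5, slow_exchange = FALSE) {
  if (!all(c("t_h", "c_ldpe_star") %in% names(obs)))
    stop("obs must have columns t_h and c_ldpe_star")
  obs <- obs[order(obs$t_h), , drop = FALSE]
  if (nrow(obs) < 4 || obs$t_h[1] != 0)
    stop("need >= 4 timepoints including t = 0")
  if (is.na(kp_fixed$k_micelle) || is.na(kp_fixed$k_oil))
    stop("kp_fixed must carry k_micelle and k_oil")

  if (is.null(s0)) {
    s0 <- initialize_state(sys, kp_fixed,
                           c_pom_star_day28 = c_pom_star_day28,
                           c_total = c_total,
                           c_ldpe_star0 = obs$c_ldpe_star[1])
  }
  t_grid <- sort(unique(c(0, obs$t_h)))

  predict_cstar <- function(lg) {
    kp <- kp_fixed
    kp$k1 <- 10^lg[1]; kp$k2 <- 10^lg[2]
    traj <- simulate_exchange(sys, kp, s0, t_grid,
                              slow_exchange = slow_exchange)
    traj$c_ldpe_star[match(obs$t_h, traj$t_h)]
  }
  resid_fn <- function(lg) {
    p <- tryCatch(predict_cstar(lg), error = function(e) NULL)
    if (is.null(p)) return(rep(1e12, nrow(obs)))
    obs$c_ldpe_star - p
  }

  lower <- c(log10_k1_bounds[1], log10_k2_bounds[1])
  upper <- c(log10_k1_bounds[2], log10_k2_bounds[2])

  starts <- list(c(mean(log10_k1_bounds), 0))
  if (!is.na(kp_fixed$k_p)) {
    # K_P ties k1 to k2; seed along that ridge
    for (lk2 in c(0, -0.5, 0.5)) {
      lk1 <- log10(kp_fixed$k_p * 10^lk2 * sys$ldpe_conc0 * kp_fixed$f1)
      starts[[length(starts) + 1]] <- c(min(max(lk1, lower[1]), upper[1]), lk2)
    }
  }
  grid <- expand.grid(l1 = seq(1, 8, by = 1.75), l2 = c(-1, 0))
  for (i in seq_len(nrow(grid)))
    starts[[length(starts) + 1]] <- as.numeric(grid[i, ])

  # rank candidate starts by a single cheap forward evaluation, then run
  # the optimiser only from the most promising ones
  ssr0 <- vapply(starts, function(st) sum(resid_fn(st)^2), numeric(1))
  starts <- starts[order(ssr0)][seq_len(min(length(starts),
                                            max(n_starts, 1)))]
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    # multi-start is a fallback: stop once an attempt has genuinely
    # improved on the best cheap start
    if (best$deviance <= min(ssr0) * (1 - 1e-6) ||
        best$deviance <= 1e-16 * sum(obs$c_ldpe_star^2)) break
  }
  if (is.null(best)) {
    return(structure(list(k1_hat = NA_real_, k2_hat = NA_real_,
                          se_k1 = NA_real_, se_k2 = NA_real_,
                          p_k1 = NA_real_, p_k2 = NA_real_,
                          kp_hat = NA_real_, convergence = "failed",
                          residuals = rep(NA_real_, nrow(obs)),
                          n_obs = nrow(obs)),
                     class = "kinetic_fit"))
  }

  lg <- best$par
  k1 <- 10^lg[1]; k2 <- 10^lg[2]
  n <- nrow(obs); p <- 2
  sigma2 <- best$deviance / max(n - p, 1)

  # asymptotic covariance in log10 space; delta method back-transform
  J <- tryCatch({
    h <- 1e-5
    base <- predict_cstar(lg)
    cbind((predict_cstar(lg + c(h, 0)) - base) / h,
          (predict_cstar(lg + c(0, h)) - base) / h)
  }, error = function(e) NULL)

  status <- "converged"
  se_lg <- c(NA_real_, NA_real_)
  if (!is.null(J) && all(is.finite(J))) {
    jtj <- crossprod(J)
    cn <- tryCatch(kappa(jtj, exact = TRUE), error = function(e) Inf)
    # near-collinear sensitivities (e.g. a flat equilibrium series pins
    # only the k1/k2 ratio) make the individual rates meaningless
    ccol <- if (stats::sd(J[, 1]) > 0 && stats::sd(J[, 2]) > 0)
      abs(stats::cor(J[, 1], J[, 2])) else 1
    if (!is.finite(cn) || cn > 1e12 || ccol > 0.9999) {
      status <- "unidentifiable"
    } else {
      cv <- sigma2 * solve(jtj)
      se_lg <- sqrt(pmax(diag(cv), 0))
    }
  }
  at_bound <- any(abs(lg - lower) < 1e-8) || any(abs(lg - upper) < 1e-8)
  if (status == "converged" && at_bound) status <- "bound"

  se_k1 <- k1 * log(10) * se_lg[1]
  se_k2 <- k2 * log(10) * se_lg[2]
  tval <- function(est, se) if (is.finite(se) && se > 0)
    2 * stats::pt(-abs(est / se), df = max(n - p, 1)) else NA_real_

  structure(list(k1_hat = k1, k2_hat = k2, se_k1 = se_k1, se_k2 = se_k2,
                 p_k1 = tval(k1, se_k1), p_k2 = tval(k2, se_k2),
                 kp_hat = derive_kp(k1, k2, sys$ldpe_conc0, kp_fixed$f1),
                 convergence = status,
                 residuals = as.numeric(resid_fn(lg)), n_obs = n),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kinetic fit (%s, n = %d):\n", x$convergence, x$n_obs))
  cat(sprintf("  k1 = %.4g (SE %.2g) 1/h, p = %.3g\n",
              x$k1_hat, x$se_k1, x$p_k1))
  cat(sprintf("  k2 = %.4g (SE %.2g) 1/h, p = %.3g\n",
              x$k2_hat, x$se_k2, x$p_k2))
  cat(sprintf("  K_P = %.4g L/kg\n", x$kp_hat))
  invisible(x)
}

#' Regress fitted rates and distribution coefficients on hydrophobicity
#'
#' Ordinary least squares of `log10 k1`, `log10 k2` and `log10 K_P`
#' against log K_OW across a congener series, the standard log-linear
#' free-energy summary of sorption kinetics.
#'
#' @param results list of `kinetic_fit` objects (one per congener), or a
#'   `data.frame` with columns `k1_hat`, `k2_hat`, `kp_hat`.
#' @param congeners a [congeners()] table matched to `results` by
#'   position.
#' @return Named list of [log_linear_relation()]s: `k1`, `k2`, `k_p`.
#' @export
regress_rates <- function(results, congeners) {
  if (is.data.frame(results)) {
    df <- results
  } else {
    df <- data.frame(
      k1_hat = vapply(results, function(r) r$k1_hat, numeric(1)),
      k2_hat = vapply(results, function(r) r$k2_hat, numeric(1)),
      kp_hat = vapply(results, function(r) r$kp_hat, numeric(1)))
  }
  if (nrow(df) != nrow(congeners))
    stop("results and congeners must match one-to-one")
  if (nrow(df) < 3) stop("need at least 3 congeners to regress")
  x <- congeners$log_kow
  list(k1 = fit_loglinear(x, log10(df$k1_hat)),
       k2 = fit_loglinear(x, log10(df$k2_hat)),
       k_p = fit_loglinear(x, log10(df$kp_hat)))
}

#' Read an LDPE observation table from CSV
#'
#' Expects columns `t_h` and `c_ldpe_ug_per_kg`, optionally `congener` and
#' `replicate`.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` with a `c_ldpe_star` column for [fit_k1k2()].
#' @export
read_ldpe_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t_h", "c_ldpe_ug_per_kg") %in% names(df)))
    stop("observations CSV must have columns t_h and c_ldpe_ug_per_kg")
  df$c_ldpe_star <- df$c_ldpe_ug_per_kg
  df
}
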
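#' Gut-fluid system configuration
#'
#' Geometry and schedule of the simulated gut digestion assay: system
#' volume, phase mass concentrations, the plastic-strip removal schedule,
#' and the digestion kinetics driving the micelle/oil pools. All mass
#' concentrations refer to the second (digestion) phase of the assay,
#' i.e. after lipase addition; `dilution_factor` records the volume step at
#' lipase addition (default 8/7, ~10 mL into ~70 mL) and is used to relate
#' pre-addition sampler readings to the digestion-phase state.
#'
#' Defaults mirror a 7 g oil / 0.7 g LDPE (10 strips) / ~80 mL system with
#' one strip removed at t = 0 and after 2, 4, 6, 8, 10, 24, 48 and 72 h of
#' digestion. The POM sampler is collected before digestion starts, so
#' `pom_conc` defaults to 0 during simulation.
#'
#' @param v_w system volume, L (digestion phase).
#' @param ldpe_conc0 initial LDPE mass concentration, kg/L (all strips).
#' @param n_strips0 initial number of identical LDPE strips.
#' @param removal_times times (h) at which one strip is removed; sorted,
#'   may include 0.
#' @param digestion a [digestion_params()].
#' @param pom_conc POM mass concentration during digestion, kg/L (0 when
#'   the sampler has been collected).
#' @param dilution_factor volume dilution applied at lipase addition.
#' @return An object of class `gut_system`.
#' @export
gut_system <- function(v_w = 0.0799,
                       ldpe_conc0 = 0.7e-3 / 0.0799,
                       n_strips0 = 10,
                       removal_times = c(0, 2, 4, 6, 8, 10, 24, 48, 72),
                       digestion = enzyme_digestion_params("high"),
                       pom_conc = 0,
                       dilution_factor = 8 / 7) {
  if (v_w <= 0) stop("v_w must be > 0")
  if (ldpe_conc0 <= 0) stop("ldpe_conc0 must be > 0")
  if (n_strips0 < 1) stop("n_strips0 must be >= 1")
  removal_times <- sort(unique(as.numeric(removal_times)))
  if (length(removal_times) > n_strips0)
    stop("more removals scheduled than strips available")
  if (any(removal_times < 0)) stop("removal_times must be >= 0")
  if (pom_conc < 0) stop("pom_conc must be >= 0")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  stopifnot(inherits(digestion, "digestion_params"))
  structure(list(v_w = v_w, ldpe_conc0 = ldpe_conc0, n_strips0 = n_strips0,
                 removal_times = removal_times, digestion = digestion,
                 pom_conc = pom_conc, dilution_factor = dilution_factor),
            class = "gut_system")
}

#' @export
print.gut_system <- function(x, ...) {
  cat(sprintf(
    "gut system: V = %.4g L, [LDPE] = %.4g kg/L (%d strips), [POM] = %.4g kg/L\n",
    x$v_w, x$ldpe_conc0, x$n_strips0, x$pom_conc))
  cat("  removals at t =", paste(x$removal_times, collapse = ", "), "h\n")
  print(x$digestion)
  invisible(x)
}

#' Freely dissolved fraction of the instantaneously equilibrating pool
#'
#' Water, micelles, oil and POM are assumed to re-equilibrate instantly
#' relative to the slow LDPE exchange. The freely dissolved share of the
#' chemical mass in that pool is
#' `f_w = 1 / (1 + K_micelle [micelle] + K_oil [oil] + K_POM [POM])`,
#' so that `C_w = f_w * (pool mass / V_w)`.
#'
#' @param kp a [kinetic_params()] carrying the partition coefficients.
#' @param micelle_conc,oil_conc,pom_conc phase mass concentrations, kg/L.
#' @return Dimensionless fraction in (0, 1].
#' @examples
#' water_fraction(kinetic_params(k_micelle = 1e5, k_oil = 0, k_pom = 0),
#'                micelle_conc = 5.7e-3, oil_conc = 0)
#' @export
water_fraction <- function(kp, micelle_conc, oil_conc, pom_conc = 0) {
  km <- ifelse(is.na(kp$k_micelle), 0, kp$k_micelle)
  ko <- ifelse(is.na(kp$k_oil), 0, kp$k_oil)
  kpom <- ifelse(is.na(kp$k_pom), 0, kp$k_pom)
  if (any(c(micelle_conc, oil_conc, pom_conc) < 0))
    stop("phase concentrations must be >= 0")
  1 / (1 + km * micelle_conc + ko * oil_conc + kpom * pom_conc)
}

#' Initial chemical state of the gut system
#'
#' Builds the chemical mass state at the start of digestion (t = 0) from
#' exactly one anchor:
#' \describe{
#'   \item{POM-anchored}{`c_pom_star_day28` (ug/kg) from the passive
#'   sampler collected after pre-equilibration gives the freely dissolved
#'   concentration `C_w = C*_POM / K_POM`; micelle- and oil-bound masses
#'   follow from `K_micelle` and `K_oil`, and the LDPE load either from a
#'   measured `c_ldpe_star0` (ug/kg) or from the `K_P` equilibrium.}
#'   \item{total-anchored}{`c_total` (ug/L) is partitioned across all
#'   phases at full equilibrium.}
#' }
#' The plastic-bound mass is split `f1 : (1 - f1)` between the fast and
#' slow reservoirs (assumed mutually equilibrated after the long
#' pre-incubation).
#'
#' @param sys a [gut_system()].
#' @param kp a [kinetic_params()] with the partition coefficients set
#'   (`k_p` may be `NA` if `k1` and `k2` are available, see [derive_kp()]).
#' @param c_pom_star_day28 sampler reading at the end of pre-equilibration,
#'   ug/kg (POM-anchored mode).
#' @param c_total total chemical concentration, ug/L of system volume
#'   (total-anchored mode).
#' @param c_ldpe_star0 optional measured LDPE concentration at t = 0,
#'   ug/kg; overrides the equilibrium LDPE load.
#' @return An object of class `system_state`: list with `t`,
#'   `m_ldpe_fast`, `m_ldpe_slow`, `m_pool`, `m_removed` (all ug),
#'   `strips_remaining` and `m_total`.
#' @export
initialize_state <- function(sys, kp, c_pom_star_day28 = NULL,
                             c_total = NULL, c_ldpe_star0 = NULL) {
  if (is.null(c_pom_star_day28) == is.null(c_total))
    stop("supply exactly one of c_pom_star_day28 or c_total")
  mass_mic <- sys$digestion$micelle0 * sys$v_w     # kg
  mass_oil <- sys$digestion$oil0 * sys$v_w         # kg
  mass_ldpe <- sys$ldpe_conc0 * sys$v_w            # kg
  mass_pom <- sys$pom_conc * sys$v_w               # kg

  k_p <- kp$k_p
  if (is.na(k_p) && !is.na(kp$k1) && !is.na(kp$k2) && kp$k2 > 0)
    k_p <- derive_kp(kp$k1, kp$k2, sys$ldpe_conc0, kp$f1)

  if (!is.null(c_pom_star_day28)) {
    if (is.na(kp$k_pom) || kp$k_pom <= 0)
      stop("POM-anchored initialisation requires k_pom > 0")
    c_w <- pom_to_water(c_pom_star_day28, kp$k_pom)  # ug/L, pre-dilution
    v_pre <- sys$v_w / sys$dilution_factor
    m_w <- c_w * v_pre
    m_mic <- kp$k_micelle * c_w * mass_mic
    m_oil <- kp$k_oil * c_w * mass_oil
    m_pom <- if (mass_pom > 0) kp$k_pom * c_w * mass_pom else 0
    if (!is.null(c_ldpe_star0)) {
      m_ldpe <- c_ldpe_star0 * mass_ldpe
    } else {
      if (is.na(k_p)) stop("need k_p (or k1, k2) or a measured c_ldpe_star0")
      m_ldpe <- k_p * c_w * mass_ldpe
    }
    m_pool <- m_w + m_mic + m_oil + m_pom
  } else {
    m_total <- c_total * sys$v_w
    f_w <- water_fraction(kp, sys$digestion$micelle0, sys$digestion$oil0,
                          sys$pom_conc)
    if (!is.null(c_ldpe_star0)) {
      m_ldpe <- c_ldpe_star0 * mass_ldpe
      if (m_ldpe > m_total) stop("measured LDPE load exceeds total mass")
    } else {
      if (is.na(k_p)) stop("need k_p (or k1, k2) or a measured c_ldpe_star0")
      w_pool <- 1 / f_w
      w_ldpe <- k_p * sys$ldpe_conc0
      m_ldpe <- m_total * w_ldpe / (w_pool + w_ldpe)
    }
    m_pool <- m_total - m_ldpe
  }

  structure(list(t = 0,
                 m_ldpe_fast = kp$f1 * m_ldpe,
                 m_ldpe_slow = (1 - kp$f1) * m_ldpe,
                 m_pool = m_pool,
                 m_removed = 0,
                 strips_remaining = sys$n_strips0,
                 m_total = m_pool + m_ldpe),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf(
    "state at t = %g h: LDPE fast %.4g ug, slow %.4g ug, pool %.4g ug\n",
    x$t, x$m_ldpe_fast, x$m_ldpe_slow, x$m_pool))
  cat(sprintf("  removed %.4g ug, strips %d, M_total %.4g ug\n",
              x$m_removed, x$strips_remaining, x$m_total))
  invisible(x)
}

# Right-hand side of the exchange ODE, in chemical mass units (ug).
# y = (m_fast, m_slow, m_pool). The pool re-equilibrates instantly, so the
# driving aqueous concentration is C_w = f_w(t) * m_pool / V_w and
#   dm_fast/dt = V_w (k1 C_w - k2 C_fast) = k1 f_w(t) m_pool - k2 m_fast.
# Integrating m_pool explicitly makes mass conservation a genuine check on
# the solver rather than an identity. Kept allocation-free: it runs at
# every internal solver step.
exchange_rhs <- function(t, y, parms) {
  ffa <- parms$ffa_max * (1 - exp(-parms$k_ffa * t))
  micelle <- parms$micelle0 + ffa * parms$mw_ffa * 1e-9
  oil <- parms$oil0 - (ffa / 3) * parms$mw_oil * 1e-9
  f_w <- 1 / (1 + parms$k_micelle * micelle + parms$k_oil * oil +
                parms$k_pom * parms$pom_conc)
  d_fast <- parms$k1 * f_w * y[3] - parms$k2 * y[1]
  d_slow <- if (parms$slow_exchange) {
    parms$k3 * ((1 - parms$f1) / parms$f1 * y[1] - y[2])
  } else 0
  list(c(d_fast, d_slow, -d_fast))
}

#' Simulate chemical exchange during digestion
#'
#' Integrates the biphasic reversible exchange of chemical between the LDPE
#' fast reservoir and the instantaneously equilibrating
#' water/micelle/oil(/POM) pool while digestion shifts the micelle and oil
#' mass concentrations, with discrete strip-removal events. The fast
#' reservoir obeys `dC_LDPE,fast/dt = k1 C_w - k2 C_LDPE,fast` on the
#' system-volume basis; the slow intrapolymer reservoir is frozen by
#' default (its 13-32 day half-life is irrelevant over 72 h) and can be
#' enabled with `slow_exchange = TRUE` for multi-week scenarios.
#'
#' At each removal time one strip leaves the system, carrying its
#' proportional share (`1/strips_remaining`) of both LDPE mass and
#' LDPE-bound chemical; solid-phase concentrations (ug/kg) are continuous
#' across the event. Integration proceeds piecewise between events
#' (lsoda, `rtol` 1e-8), so stored values are independent of the output
#' grid resolution. Rows at a removal time report the pre-removal state
#' (what a strip collected at that instant measures).
#'
#' @param sys a [gut_system()].
#' @param kp a [kinetic_params()] with `k1`, `k2`, the partition
#'   coefficients, `f1` and `k3` set.
#' @param s0 a `system_state` from [initialize_state()].
#' @param t_grid increasing output times (h), starting at 0.
#' @param slow_exchange enable slow-reservoir exchange (default `FALSE`).
#' @param rtol,atol solver tolerances.
#' @return A `data.frame` of class `gut_trajectory`, one row per output
#'   time, with chemical masses (ug), system-basis concentrations
#'   `c_w`, `c_micelle`, `c_oil`, `c_pom`, `c_ldpe` (ug/L), solid-basis
#'   concentrations `c_micelle_star`, `c_oil_star`, `c_ldpe_star` (ug/kg),
#'   phase mass concentrations (kg/L) and bookkeeping columns. The removal
#'   event log is in `attr(, "removals")`.
#' @export
simulate_exchange <- function(sys, kp, s0, t_grid,
                              slow_exchange = FALSE,
                              rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(sys, "gut_system"), inherits(kp, "kinetic_params"),
            inherits(s0, "system_state"))
  if (is.unsorted(t_grid, strictly = TRUE) || t_grid[1] != 0)
    stop("t_grid must be strictly increasing and start at 0")
  if (is.na(kp$k1) || is.na(kp$k2)) stop("k1 and k2 must be set")
  t_end <- max(t_grid)
  if (is.null(atol)) atol <- 1e-12 * max(s0$m_total, 1)

  dig <- sys$digestion
  # check once that the oil pool stays non-negative over the horizon
  compartments_at(t_end, dig)
  parms <- list(k1 = kp$k1, k2 = kp$k2, k3 = kp$k3, f1 = kp$f1,
                k_micelle = ifelse(is.na(kp$k_micelle), 0, kp$k_micelle),
                k_oil = ifelse(is.na(kp$k_oil), 0, kp$k_oil),
                k_pom = ifelse(is.na(kp$k_pom), 0, kp$k_pom),
                pom_conc = sys$pom_conc,
                ffa_max = dig$ffa_max, k_ffa = dig$k_ffa,
                mw_ffa = dig$mw_ffa, mw_oil = dig$mw_oil,
                micelle0 = dig$micelle0, oil0 = dig$oil0,
                slow_exchange = slow_exchange)

  removals <- sys$removal_times[sys$removal_times <= t_end]
  seg_bounds <- sort(unique(c(0, removals[removals > 0], t_end)))

  y <- c(s0$m_ldpe_fast, s0$m_ldpe_slow, s0$m_pool)
  strips <- s0$strips_remaining
  m_removed <- s0$m_removed
  rows <- list()
  ev_log <- list()

  store_row <- function(t, y, strips, m_removed) {
    comp <- compartments_at(t, sys$digestion)
    ldpe_conc <- sys$ldpe_conc0 * strips / sys$n_strips0
    f_w <- 1 / (1 + parms$k_micelle * comp$micelle_conc +
                  parms$k_oil * comp$oil_conc +
                  parms$k_pom * parms$pom_conc)
    c_w <- f_w * y[3] / sys$v_w
    m_ldpe <- y[1] + y[2]
    data.frame(
      t_h = t, strips_remaining = strips,
      m_ldpe_fast = y[1], m_ldpe_slow = y[2], m_pool = y[3],
      m_removed = m_removed, m_total = s0$m_total,
      micelle_conc = comp$micelle_conc, oil_conc = comp$oil_conc,
      pom_conc = parms$pom_conc, ldpe_conc = ldpe_conc,
      c_w = c_w,
      c_micelle = parms$k_micelle * comp$micelle_conc * c_w,
      c_oil = parms$k_oil * comp$oil_conc * c_w,
      c_pom = parms$k_pom * parms$pom_conc * c_w,
      c_ldpe = m_ldpe / sys$v_w,
      c_micelle_star = parms$k_micelle * c_w,
      c_oil_star = parms$k_oil * c_w,
      c_pom_star = parms$k_pom * c_w,
      c_ldpe_star = if (ldpe_conc > 0) m_ldpe / sys$v_w / ldpe_conc
                    else NA_real_
    )
  }

  remove_strip <- function(t) {
    if (strips < 1) stop("no strips left to remove at t = ", t)
    share <- 1 / strips
    chem_out <- share * (y[1] + y[2])
    ev_log[[length(ev_log) + 1]] <<- data.frame(
      t_h = t, strips_before = strips, chem_removed_ug = chem_out,
      ldpe_removed_kg = sys$ldpe_conc0 * sys$v_w / sys$n_strips0)
    y[1] <<- y[1] * (1 - share)
    y[2] <<- y[2] * (1 - share)
    m_removed <<- m_removed + chem_out
    strips <<- strips - 1
  }

  # output at t = 0 (pre-removal), then apply a t = 0 removal if scheduled
  if (0 %in% t_grid) rows[[length(rows) + 1]] <- store_row(0, y, strips, m_removed)
  if (0 %in% removals) remove_strip(0)

  for (i in seq_len(length(seg_bounds) - 1)) {
    a <- seg_bounds[i]; b <- seg_bounds[i + 1]
    inner <- t_grid[t_grid > a & t_grid < b]
    times <- sort(unique(c(a, inner, b)))
    sol <- deSolve::ode(y = y, times = times, func = exchange_rhs,
                        parms = parms, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failed on [", a, ", ", b, "] h (istate = ",
           attr(sol, "istate")[1], ")")
    for (t_out in times[-1]) {
      if (t_out %in% t_grid) {
        yy <- sol[sol[, "time"] == t_out, -1]
        rows[[length(rows) + 1]] <- store_row(t_out, yy, strips, m_removed)
      }
    }
    y <- unname(sol[nrow(sol), -1])
    if (b %in% removals) remove_strip(b)
  }

  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  attr(traj, "removals") <- if (length(ev_log)) do.call(rbind, ev_log)
                            else data.frame()
  attr(traj, "sys") <- sys
  attr(traj, "kp") <- kp
  attr(traj, "s0") <- s0
  class(traj) <- c("gut_trajectory", "data.frame")
  traj
}

#' Reshape a trajectory to long (tidy) form
#'
#' One row per (time, phase, basis), convenient for CSV export and
#' plotting.
#'
#' @param traj a `gut_trajectory` from [simulate_exchange()].
#' @return A `data.frame` with columns `t_h`, `phase`, `basis`, `value`.
#' @export
trajectory_long <- function(traj) {
  sysv <- c(c_w = "water", c_micelle = "micelle", c_oil = "oil",
            c_pom = "pom", c_ldpe = "ldpe")
  solid <- c(c_micelle_star = "micelle", c_oil_star = "oil",
             c_pom_star = "pom", c_ldpe_star = "ldpe")
  out <- rbind(
    do.call(rbind, lapply(names(sysv), function(cl)
      data.frame(t_h = traj$t_h, phase = sysv[[cl]],
                 basis = "system_ug_per_L", value = traj[[cl]]))),
    do.call(rbind, lapply(names(solid), function(cl)
      data.frame(t_h = traj$t_h, phase = solid[[cl]],
                 basis = "solid_ug_per_kg", value = traj[[cl]])))
  )
  rownames(out) <- NULL
  out
}

#' Fold increase of plastic-bound chemical concentration
#'
#' Ratio of the solid-basis LDPE concentration (ug/kg) at the end of the
#' trajectory to its initial value. For a system started at its kinetic
#' equilibrium with no digestion this is 1; when the plastic starts below
#' the `k1/k2` equilibrium it approaches `C_eq / C_0` as the system
#' relaxes.
#'
#' @param traj a `gut_trajectory`.
#' @return Dimensionless fold increase.
#' @export
fold_increase <- function(traj) {
  if (nrow(traj) < 1) stop("empty trajectory")
  c0 <- traj$c_ldpe_star[1]
  if (!is.finite(c0) || c0 <= 0)
    stop("initial solid-basis LDPE concentration must be > 0")
  traj$c_ldpe_star[nrow(traj)] / c0
}

#' Percent reduction in chemical bioavailability
#'
#' Share of the total gut chemical newly sequestered by the plastic over
#' the trajectory: `100 * (m_LDPE(t_end) - m_LDPE(0)) / M_total`. Plastic
#' (and the chemical it carries) is not absorbed across the gut lining, so
#' this is the percentage of gut chemical made unavailable for uptake
#' relative to a plastic-free gut. With `count_removed = TRUE` (default)
#' chemical that left the system on removed strips counts as sequestered.
#'
#' @param traj a `gut_trajectory`.
#' @param count_removed count chemical on removed strips as sequestered.
#' @return Percent, in `[-100, 100]`.
#' @export
bioavailability_reduction <- function(traj, count_removed = TRUE) {
  if (nrow(traj) < 1) stop("empty trajectory")
  last <- nrow(traj)
  m0 <- traj$m_ldpe_fast[1] + traj$m_ldpe_slow[1]
  m_end <- traj$m_ldpe_fast[last] + traj$m_ldpe_slow[last]
  if (count_removed) m_end <- m_end + traj$m_removed[last]
  100 * (m_end - m0) / traj$m_total[1]
}
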
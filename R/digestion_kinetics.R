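#' Lipid digestion parameters
#'
#' Parameters of first-order free-fatty-acid (FFA) liberation by lipase and
#' of the resulting time-varying micelle and oil pools. Lipolysis of
#' triglycerides liberates FFA following a saturating first-order law with
#' rate `k_ffa` and plateau `ffa_max`; each liberated FFA joins the mixed
#' micelle pool and each three FFA consume one triglyceride from the oil
#' pool.
#'
#' The triglyceride molecular weight defaults to the glycerol-backbone
#' relation `MW_oil = 3 MW_FFA + MW_glycerol - 3 MW_water = 3 MW_FFA +
#' 38.05 g/mol`, with `MW_FFA` defaulting to oleic acid (282.46 g/mol), the
#' dominant acid of olive oil. Both are overridable when a measured fatty
#' acid composition is available.
#'
#' @param ffa_max maximum liberated FFA concentration, uM.
#' @param k_ffa first-order liberation rate constant, 1/h; must be > 0.
#' @param mw_ffa average FFA molecular weight, g/mol.
#' @param mw_oil triglyceride molecular weight, g/mol.
#' @param micelle0 baseline (bile salt only) micelle mass concentration,
#'   kg/L of system volume.
#' @param oil0 initial oil mass concentration, kg/L of system volume.
#' @return An object of class `digestion_params`.
#' @examples
#' digestion_params(ffa_max = 10.53, k_ffa = 0.079)
#' @export
digestion_params <- function(ffa_max, k_ffa, mw_ffa = 282.46,
                             mw_oil = 3 * mw_ffa + 38.05,
                             micelle0 = 5.7e-3, oil0 = 8.76e-2) {
  if (!is.finite(ffa_max) || ffa_max < 0) stop("ffa_max must be >= 0")
  if (!is.finite(k_ffa) || k_ffa <= 0) stop("k_ffa must be > 0")
  if (micelle0 < 0 || oil0 < 0) stop("micelle0 and oil0 must be >= 0")
  structure(list(ffa_max = ffa_max, k_ffa = k_ffa, mw_ffa = mw_ffa,
                 mw_oil = mw_oil, micelle0 = micelle0, oil0 = oil0),
            class = "digestion_params")
}

#' @export
print.digestion_params <- function(x, ...) {
  cat(sprintf(
    "digestion: FFA_max = %.4g uM, k_FFA = %.4g 1/h, MW_FFA = %.4g g/mol\n",
    x$ffa_max, x$k_ffa, x$mw_ffa))
  cat(sprintf("  micelle0 = %.4g kg/L, oil0 = %.4g kg/L\n",
              x$micelle0, x$oil0))
  invisible(x)
}

#' Enzyme-activity presets for the simulated gut fluid assay
#'
#' Digestion parameter sets for the high and low enzyme-activity
#' treatments of the simulated gut fluid assay, as fitted from
#' pH-derived FFA time series: high activity `FFA_max = 10.53` uM,
#' `k_FFA = 0.079` 1/h; low activity `FFA_max = 1.18` uM,
#' `k_FFA = 1.22` 1/h. The low-activity rate constant is poorly
#' identified (sparse sampling in the first 2 h) but is reproduced
#' as fitted.
#'
#' @param level `"high"` or `"low"`.
#' @param ... overrides passed to [digestion_params()].
#' @return A [digestion_params()] object.
#' @export
enzyme_digestion_params <- function(level = c("high", "low"), ...) {
  level <- match.arg(level)
  if (level == "high") digestion_params(ffa_max = 10.53, k_ffa = 0.079, ...)
  else digestion_params(ffa_max = 1.18, k_ffa = 1.22, ...)
}

#' Liberated FFA concentration at time t
#'
#' Saturating first-order liberation: `FFA(t) = FFA_max (1 - exp(-k_FFA t))`,
#' the solution of `d[FFA]/dt = k_FFA (FFA_max - [FFA])` with `FFA(0) = 0`.
#' Monotone non-decreasing with limit `FFA_max`.
#'
#' @param t time(s), hours; must be >= 0.
#' @param p a [digestion_params()].
#' @return FFA concentration(s), uM.
#' @examples
#' ffa_at(24, enzyme_digestion_params("high"))
#' @export
ffa_at <- function(t, p) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  p$ffa_max * (1 - exp(-p$k_ffa * t))
}

#' Convert pH time series to liberated FFA
#'
#' Each FFA liberated releases one proton, so the liberated FFA molar
#' concentration is approximated by the increase in free proton
#' concentration relative to the starting pH:
#' `[FFA] = (10^(-pH_t) - 10^(-pH_0)) * 1e6` uM. Buffering by protein and
#' bile salts is ignored; when an FFA assay is available it should be
#' preferred for inference. Non-physical readings (pH rising above the
#' baseline) are floored at zero and flagged.
#'
#' @param ph0 starting pH, in (0, 14).
#' @param ph_t vector of observed pH values, in (0, 14).
#' @return A `data.frame` with columns `ffa` (uM) and `flag` (`"ok"` or
#'   `"nonphysical"`).
#' @examples
#' ph_to_ffa(6.08, c(6.05, 6.00))
#' @export
ph_to_ffa <- function(ph0, ph_t) {
  if (ph0 <= 0 || ph0 >= 14 || any(ph_t <= 0) || any(ph_t >= 14))
    stop("pH values must lie in (0, 14)")
  ffa <- (10^(-ph_t) - 10^(-ph0)) * 1e6
  flag <- ifelse(ffa < 0, "nonphysical", "ok")
  if (any(ffa < 0))
    warning("pH above baseline at ", sum(ffa < 0),
            " timepoint(s); floored at 0")
  data.frame(ffa = pmax(ffa, 0), flag = flag, stringsAsFactors = FALSE)
}

#' Micelle and oil mass concentrations during digestion
#'
#' As FFA is liberated the amphiphilic molecules join the mixed micelle
#' pool and the triglyceride oil pool shrinks by one mole per three moles
#' of FFA:
#' `[micelle]_t = micelle0 + FFA(t) * MW_FFA * 1e-9` and
#' `[oil]_t = oil0 - (FFA(t)/3) * MW_oil * 1e-9` (uM * g/mol = ug/L =
#' 1e-9 kg/L). Parameters that would drive the oil pool negative are an
#' error.
#'
#' @param t time(s), hours; must be >= 0.
#' @param p a [digestion_params()].
#' @return A `data.frame` with columns `t`, `micelle_conc`, `oil_conc`
#'   (kg/L).
#' @export
compartments_at <- function(t, p) {
  ffa <- ffa_at(t, p)
  micelle <- p$micelle0 + ffa * p$mw_ffa * 1e-9
  oil <- p$oil0 - (ffa / 3) * p$mw_oil * 1e-9
  if (any(oil < 0))
    stop("oil pool would be depleted below zero; ",
         "ffa_max is inconsistent with oil0")
  data.frame(t = t, micelle_conc = micelle, oil_conc = oil)
}

#' Fit first-order FFA liberation kinetics
#'
#' Nonlinear least-squares fit of `FFA(t) = FFA_max (1 - exp(-k_FFA t))` to
#' an observed FFA (or pH-derived FFA) time series. Initialisation uses
#' `FFA_max = max(observed)` and `k_FFA = 1 / t_half_rise` (the first time
#' the series passes half its maximum); if the fit fails to converge, a
#' multi-start sweep over `k_FFA` in `10^[-3, 1]` is attempted. A series
#' with no signal is returned with `convergence = "degenerate"` (plateau 0,
#' rate unidentifiable) rather than silently defaulting.
#'
#' @param times observation times, hours (at least 3, at least one > 0).
#' @param ffa observed FFA concentrations, uM.
#' @return An object of class `ffa_fit`: list with `ffa_max`, `k_ffa`,
#'   `se_ffa_max`, `se_k_ffa`, `convergence` (`"converged"`, `"failed"` or
#'   `"degenerate"`), `residuals` and `n_obs`.
#' @examples
#' t <- c(0, 2, 4, 6, 8, 10, 24, 48, 72)
#' fit_ffa(t, ffa_at(t, enzyme_digestion_params("high")))
#' @export
fit_ffa <- function(times, ffa) {
  keep <- is.finite(times) & is.finite(ffa)
  times <- times[keep]; ffa <- ffa[keep]
  if (length(times) < 3 || !any(times > 0))
    stop("need >= 3 points with at least one t > 0")

  res <- function(fmax, k) ffa - fmax * (1 - exp(-k * times))
  if (max(abs(ffa)) == 0 || stats::sd(ffa) == 0) {
    return(structure(list(ffa_max = max(ffa), k_ffa = NA_real_,
                          se_ffa_max = NA_real_, se_k_ffa = NA_real_,
                          convergence = "degenerate",
                          residuals = res(max(ffa), 1), n_obs = length(times)),
                     class = "ffa_fit"))
  }

  fmax0 <- max(ffa)
  half_idx <- which(ffa >= fmax0 / 2 & times > 0)
  k0 <- if (length(half_idx)) 1 / times[min(half_idx)] else 0.1

  try_fit <- function(fmax_start, k_start) {
    tryCatch(
      minpack.lm::nlsLM(
        ffa ~ fmax * (1 - exp(-k * times)),
        start = list(fmax = fmax_start, k = k_start),
        lower = c(fmax = 0, k = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  fit <- try_fit(fmax0, k0)
  if (is.null(fit)) {
    for (k_start in 10^seq(-3, 1, length.out = 9)) {
      fit <- try_fit(fmax0, k_start)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) {
    return(structure(list(ffa_max = NA_real_, k_ffa = NA_real_,
                          se_ffa_max = NA_real_, se_k_ffa = NA_real_,
                          convergence = "failed", residuals = rep(NA_real_,
                          length(times)), n_obs = length(times)),
                     class = "ffa_fit"))
  }
  co <- summary(fit)$coefficients
  structure(list(ffa_max = unname(co["fmax", "Estimate"]),
                 k_ffa = unname(co["k", "Estimate"]),
                 se_ffa_max = unname(co["fmax", "Std. Error"]),
                 se_k_ffa = unname(co["k", "Std. Error"]),
                 convergence = "converged",
                 residuals = as.numeric(stats::residuals(fit)),
                 n_obs = length(times)),
            class = "ffa_fit")
}

#' @export
print.ffa_fit <- function(x, ...) {
  cat(sprintf("FFA kinetics fit (%s, n = %d):\n", x$convergence, x$n_obs))
  cat(sprintf("  FFA_max = %.4g (SE %.2g) uM\n", x$ffa_max, x$se_ffa_max))
  cat(sprintf("  k_FFA   = %.4g (SE %.2g) 1/h\n", x$k_ffa, x$se_k_ffa))
  invisible(x)
}

#' Read an FFA (or pH) time series from CSV
#'
#' Expects columns `time_h` and either `ffa_uM` or `ph` (the latter is
#' converted with [ph_to_ffa()] using the first reading as baseline).
#'
#' @param path path to a CSV file.
#' @param ph0 baseline pH used when the file carries a `ph` column;
#'   defaults to the first reading.
#' @return A `data.frame` with columns `time_h` and `ffa_uM`.
#' @export
read_ffa_series <- function(path, ph0 = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_h" %in% names(df)) stop("CSV must have a time_h column")
  if ("ffa_uM" %in% names(df)) {
    data.frame(time_h = df$time_h, ffa_uM = df$ffa_uM)
  } else if ("ph" %in% names(df)) {
    if (is.null(ph0)) ph0 <- df$ph[1]
    conv <- ph_to_ffa(ph0, df$ph)
    data.frame(time_h = df$time_h, ffa_uM = conv$ffa)
  } else {
    stop("CSV must have an ffa_uM or ph column")
  }
}
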
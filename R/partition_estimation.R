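#' Partition experiment table
#'
#' One row per (congener x replicate x phase-concentration level) of a
#' closed-tube passive-sampler partitioning experiment. The chemical is
#' spiked at total concentration `c_init` (ug/L of system volume) and, after
#' equilibration, the sampler reading `c_pom_star` (ug/kg POM) together with
#' the known POM-water partition coefficient `k_pom` (L/kg) anchors the
#' freely dissolved concentration. Phase mass concentrations are per litre
#' of system volume (kg/L).
#'
#' @param c_init total initial chemical concentration, ug/L system volume.
#' @param c_pom_star chemical concentration in the POM sampler, ug/kg.
#' @param k_pom POM-water partition coefficient, L/kg.
#' @param pom_conc POM mass concentration, kg/L.
#' @param micelle_conc micelle mass concentration, kg/L.
#' @param oil_conc oil mass concentration, kg/L.
#' @param id optional congener label.
#' @param log_kow optional hydrophobicity covariate.
#' @return A `data.frame` with one row per experiment.
#' @export
partition_experiment <- function(c_init, c_pom_star, k_pom, pom_conc,
                                 micelle_conc = 0, oil_conc = 0,
                                 id = NA_character_, log_kow = NA_real_) {
  df <- data.frame(id = id, log_kow = log_kow, c_init = c_init,
                   c_pom_star = c_pom_star, k_pom = k_pom,
                   pom_conc = pom_conc, micelle_conc = micelle_conc,
                   oil_conc = oil_conc, stringsAsFactors = FALSE)
  if (any(df$pom_conc <= 0)) stop("pom_conc must be > 0")
  num <- c("c_init", "c_pom_star", "k_pom", "micelle_conc", "oil_conc")
  if (any(unlist(df[num]) < 0)) stop("concentrations must be >= 0")
  df
}

#' Freely dissolved concentration from a POM sampler reading
#'
#' Inverts the equilibrium sampler relation `C*_POM = K_POM * C_w`:
#' the freely dissolved aqueous concentration is `C*_POM / K_POM`.
#'
#' @param c_pom_star sampler reading, ug/kg POM.
#' @param k_pom POM-water partition coefficient, L/kg; must be > 0.
#' @return Freely dissolved concentration `C_w`, ug/L.
#' @examples
#' pom_to_water(5e5, 2e5)
#' @export
pom_to_water <- function(c_pom_star, k_pom) {
  if (any(!is.finite(k_pom)) || any(k_pom <= 0))
    stop("k_pom must be finite and > 0")
  c_pom_star / k_pom
}

#' Micelle-water partition coefficient from the closed-system mass balance
#'
#' In a closed tube the spiked chemical distributes over water, POM and
#' micelles, so `C_init = C_w (1 + K_POM [POM] + K_micelle [micelle])`.
#' With `C_w` anchored by the sampler ([pom_to_water()]), the unique
#' rearrangement for the micelle-water coefficient is
#' `K_micelle = (C_init / C_w - 1 - K_POM [POM]) / [micelle]`.
#'
#' A negative estimate signals a measurement inconsistency (e.g. noise
#' driving the sampler reading above what the spike can support); it is
#' reported as-is with `flag = "negative"` rather than clipped.
#'
#' @param exp a `data.frame` as returned by [partition_experiment()] (or
#'   with the same columns), with `micelle_conc > 0`.
#' @return `exp` with columns `k_micelle` (L/kg) and `flag` (`"ok"` or
#'   `"negative"`) appended.
#' @export
estimate_k_micelle <- function(exp) {
  if (any(exp$micelle_conc <= 0))
    stop("micelle_conc must be > 0 to estimate K_micelle")
  if (any(exp$c_pom_star <= 0))
    stop("c_pom_star must be > 0 to estimate K_micelle")
  c_w <- pom_to_water(exp$c_pom_star, exp$k_pom)
  est <- (exp$c_init / c_w - 1 - exp$k_pom * exp$pom_conc) / exp$micelle_conc
  exp$k_micelle <- est
  exp$flag <- ifelse(est < 0, "negative", "ok")
  exp
}

#' Oil-water partition coefficient from the closed-system mass balance
#'
#' As [estimate_k_micelle()], with the oil phase added to the balance and
#' the micelle contribution subtracted using a known (typically pooled
#' regression) micelle-water coefficient:
#' `K_oil = (C_init / C_w - 1 - K_POM [POM] - K_micelle [micelle]) / [oil]`.
#' The oil tubes also contain the baseline bile-salt micelle pool, so
#' `micelle_conc` may be non-zero.
#'
#' @param exp a `data.frame` of experiments with `oil_conc > 0`.
#' @param k_micelle micelle-water partition coefficient(s), L/kg (scalar or
#'   one per row).
#' @return `exp` with columns `k_oil` (L/kg) and `flag` appended.
#' @export
estimate_k_oil <- function(exp, k_micelle) {
  if (any(exp$oil_conc <= 0)) stop("oil_conc must be > 0 to estimate K_oil")
  if (any(exp$c_pom_star <= 0))
    stop("c_pom_star must be > 0 to estimate K_oil")
  c_w <- pom_to_water(exp$c_pom_star, exp$k_pom)
  est <- (exp$c_init / c_w - 1 - exp$k_pom * exp$pom_conc -
            k_micelle * exp$micelle_conc) / exp$oil_conc
  exp$k_oil <- est
  exp$flag <- ifelse(est < 0, "negative", "ok")
  exp
}

#' Ordinary least-squares log-linear fit
#'
#' Fits `y = slope * x + intercept` by OLS, where `x` is log K_OW and `y`
#' the log10 of a partition coefficient or rate constant. Degenerate `x`
#' (zero variance) is an error.
#'
#' @param x numeric vector, log K_OW.
#' @param y numeric vector, log10 of the target quantity.
#' @return A [log_linear_relation()] carrying coefficient standard errors,
#'   `r2` and `n`.
#' @examples
#' fit_loglinear(c(5, 6, 7), c(5.6, 6.6, 7.6))
#' @export
fit_loglinear <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 finite (x, y) pairs")
  if (stats::sd(x) == 0) stop("x has zero variance; slope is not identifiable")
  fit <- stats::lm(y ~ x)
  # noiseless round-trips legitimately produce perfect fits
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- sm$coefficients
  se_int <- if (nrow(co) >= 1) co["(Intercept)", "Std. Error"] else NA_real_
  se_slp <- if ("x" %in% rownames(co)) co["x", "Std. Error"] else NA_real_
  r2 <- sm$r.squared
  log_linear_relation(
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r2 = if (is.finite(r2)) min(max(r2, 0), 1) else NA_real_,
    n = length(x), se_slope = se_slp, se_intercept = se_int
  )
}

#' Grouped and pooled log-linear fits
#'
#' Fits the log-linear relation separately within each level of a grouping
#' variable (e.g. phase mass-concentration level) and pooled across all
#' rows, mirroring the per-level and pooled regressions reported for
#' partition-coefficient studies.
#'
#' @param x,y as in [fit_loglinear()].
#' @param group grouping vector (coerced to factor).
#' @return Named list of [log_linear_relation()]s, one per group level,
#'   plus `$pooled`.
#' @export
fit_loglinear_groups <- function(x, y, group) {
  group <- as.factor(group)
  fits <- lapply(split(data.frame(x = x, y = y), group),
                 function(d) fit_loglinear(d$x, d$y))
  fits$pooled <- fit_loglinear(x, y)
  fits
}

#' Read a partition-experiment table from CSV
#'
#' Expects columns `c_init`, `c_pom_star`, `k_pom`, `pom_conc`,
#' `micelle_conc`, `oil_conc`, optionally `id`, `log_kow`, `level`,
#' `replicate`.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` of partition experiments.
#' @export
read_partition_experiments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("c_init", "c_pom_star", "k_pom", "pom_conc",
            "micelle_conc", "oil_conc")
  if (!all(need %in% names(df)))
    stop("partition CSV must have columns: ", paste(need, collapse = ", "))
  df
}
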
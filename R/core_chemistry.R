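#' Congener table
#'
#' Builds the table of chemical congeners that every downstream regression
#' and simulation is indexed by. Each congener carries its hydrophobicity
#' covariate (log10 octanol-water partition coefficient, `log_kow`) and the
#' total initial chemical concentration in the system, `c_total`, expressed
#' per litre of system volume.
#'
#' @param id character vector of short congener labels (e.g. `"PCB153"`).
#' @param log_kow numeric vector, log10 octanol-water partition coefficient
#'   (dimensionless). Must be finite.
#' @param c_total numeric vector, total initial chemical concentration in the
#'   system (ug per L of system volume). Must be non-negative. This is the
#'   `C_total` of the mass-conservation balance and the `C_init` of the
#'   partition experiments.
#' @return A `data.frame` with columns `id`, `log_kow`, `c_total` and class
#'   `congener_table`.
#' @examples
#' congeners(c("A", "B"), c(5.24, 8.18), c(30, 124))
#' @export
congeners <- function(id, log_kow, c_total) {
  id <- as.character(id)
  log_kow <- as.numeric(log_kow)
  c_total <- as.numeric(c_total)
  n <- length(id)
  if (length(log_kow) != n || length(c_total) != n)
    stop("id, log_kow and c_total must have equal length")
  if (any(!is.finite(log_kow))) stop("log_kow must be finite")
  if (any(!is.finite(c_total)) || any(c_total < 0))
    stop("c_total must be finite and >= 0")
  out <- data.frame(id = id, log_kow = log_kow, c_total = c_total,
                    stringsAsFactors = FALSE)
  class(out) <- c("congener_table", "data.frame")
  out
}

#' Read a congener table from CSV
#'
#' Expects a header `id,log_kow,c_total_ug_per_L`.
#'
#' @param path path to a CSV file.
#' @return A `congener_table` (see [congeners()]).
#' @export
read_congeners <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "log_kow", "c_total_ug_per_L")
  if (!all(need %in% names(df)))
    stop("congener CSV must have columns: ", paste(need, collapse = ", "))
  congeners(df$id, df$log_kow, df$c_total_ug_per_L)
}

#' Log-linear free-energy relationship
#'
#' A straight line in log10 space relating a partition coefficient or rate
#' constant to log K_OW: `log10(Q) = slope * log_kow + intercept`. These
#' one-parameter-family relationships are the standard way partitioning
#' properties of hydrophobic organic chemicals are summarised and
#' extrapolated across a homologous series.
#'
#' @param slope dimensionless slope.
#' @param intercept intercept, in log10 units of the target quantity.
#' @param r2 coefficient of determination of the underlying fit, in `[0, 1]`
#'   (optional, `NA` for a postulated relation).
#' @param n number of observations behind the fit (optional).
#' @param se_slope,se_intercept standard errors of the coefficients
#'   (optional).
#' @return An object of class `log_linear_relation`.
#' @examples
#' rel <- log_linear_relation(0.99, 0.61, r2 = 0.86)
#' predict(rel, 6.71)
#' @export
log_linear_relation <- function(slope, intercept, r2 = NA_real_,
                                n = NA_integer_, se_slope = NA_real_,
                                se_intercept = NA_real_) {
  stopifnot(is.finite(slope), is.finite(intercept))
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop("r2 must lie in [0, 1]")
  structure(
    list(slope = slope, intercept = intercept, r2 = r2, n = n,
         se_slope = se_slope, se_intercept = se_intercept),
    class = "log_linear_relation"
  )
}

#' @export
print.log_linear_relation <- function(x, ...) {
  cat(sprintf("log-linear relation: y = %.4g * log Kow + %.4g\n",
              x$slope, x$intercept))
  if (!is.na(x$r2)) cat(sprintf("  r2 = %.3f", x$r2))
  if (!is.na(x$n)) cat(sprintf("  n = %d", as.integer(x$n)))
  if (!is.na(x$r2) || !is.na(x$n)) cat("\n")
  invisible(x)
}

#' @export
predict.log_linear_relation <- function(object, log_kow, ...) {
  object$slope * log_kow + object$intercept
}

#' Evaluate a log-linear relation
#'
#' Returns `slope * log_kow + intercept`, i.e. the predicted log10 of the
#' target quantity (partition coefficient or rate constant) at the given
#' hydrophobicity.
#'
#' @param rel a [log_linear_relation()].
#' @param log_kow numeric vector of log10 octanol-water partition
#'   coefficients.
#' @return Numeric vector of predicted log10 quantities.
#' @examples
#' predict_log_quantity(log_linear_relation(0.85, 2.21), 6.71)
#' @export
predict_log_quantity <- function(rel, log_kow) {
  stopifnot(inherits(rel, "log_linear_relation"))
  predict(rel, log_kow)
}

#' Oil-over-octanol enrichment factor
#'
#' Multiplicative enrichment of the oil-water partition coefficient over
#' K_OW at a given hydrophobicity: `10^(log K_oil - log K_OW)` with
#' `log K_oil` taken from the oil-water log-linear relation. Triglyceride
#' oils sorb hydrophobic chemicals more strongly than octanol, so this
#' factor is typically well above 1; with a relation slope below 1 it
#' decreases as log K_OW grows.
#'
#' @param rel_oil the oil-water [log_linear_relation()].
#' @param log_kow numeric vector of log10 octanol-water partition
#'   coefficients.
#' @return Numeric vector of dimensionless enrichment factors.
#' @examples
#' oil_kow_enrichment(log_linear_relation(0.85, 2.21), 6.71)
#' @export
oil_kow_enrichment <- function(rel_oil, log_kow) {
  10^(predict_log_quantity(rel_oil, log_kow) - log_kow)
}

#' First-order half-life
#'
#' Half-life `ln(2) / k` of a first-order process with rate constant `k`
#' (per hour), e.g. the desorption half-life implied by a fitted fast
#' desorption rate constant.
#'
#' @param k positive rate constant, 1/h.
#' @return Half-life in hours.
#' @examples
#' first_order_half_life(0.283)
#' @export
first_order_half_life <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop("k must be finite and > 0")
  log(2) / k
}

#' Kinetic and partitioning parameter set for one congener
#'
#' Collects the biphasic sorption rate constants and the partition
#' coefficients of a single chemical. The fast reservoir of the polymer
#' exchanges with water at uptake rate `k1` and desorption rate `k2`
#' (both 1/h, acting on system-volume concentrations); the slow
#' intrapolymer reservoir holds a fraction `1 - f1` of plastic-bound
#' chemical and exchanges at rate `k3`. `k_pom`, `k_micelle` and `k_oil`
#' are the phase-water partition coefficients (L/kg); `k_p` is the derived
#' whole-polymer plastic-water distribution coefficient (L/kg, see
#' [derive_kp()]).
#'
#' @param k1 fast uptake rate constant, 1/h.
#' @param k2 fast desorption rate constant, 1/h.
#' @param k3 slow intrapolymer rate constant, 1/h. Default corresponds to a
#'   20-day half-life, the midpoint of reported 13-32 day intrapolymer
#'   half-lives for thin LDPE; over a 72 h digestion it is negligible.
#' @param f1 fast-reservoir fraction of plastic-bound chemical, in `(0, 1]`.
#' @param k_pom,k_micelle,k_oil phase-water partition coefficients, L/kg.
#' @param k_p whole-polymer plastic-water distribution coefficient, L/kg
#'   (optional; computable from `k1`, `k2` via [derive_kp()]).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k1 = NA_real_, k2 = NA_real_,
                           k3 = log(2) / (20 * 24), f1 = 0.5,
                           k_pom = NA_real_, k_micelle = NA_real_,
                           k_oil = NA_real_, k_p = NA_real_) {
  rates <- c(k1 = k1, k2 = k2, k3 = k3)
  if (any(!is.na(rates) & rates < 0)) stop("rate constants must be >= 0")
  if (!is.finite(f1) || f1 <= 0 || f1 > 1) stop("f1 must lie in (0, 1]")
  ks <- c(k_pom = k_pom, k_micelle = k_micelle, k_oil = k_oil, k_p = k_p)
  if (any(!is.na(ks) & ks < 0)) stop("partition coefficients must be >= 0")
  structure(list(k1 = k1, k2 = k2, k3 = k3, f1 = f1, k_pom = k_pom,
                 k_micelle = k_micelle, k_oil = k_oil, k_p = k_p),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("kinetic parameters:\n")
  cat(sprintf("  k1 = %.4g 1/h, k2 = %.4g 1/h, k3 = %.4g 1/h, f1 = %.3g\n",
              x$k1, x$k2, x$k3, x$f1))
  cat(sprintf("  K_POM = %.4g, K_micelle = %.4g, K_oil = %.4g, K_P = %.4g L/kg\n",
              x$k_pom, x$k_micelle, x$k_oil, x$k_p))
  invisible(x)
}

#' Default substitute relation for the POM-water partition coefficient
#'
#' The polyoxymethylene (POM) passive-sampler partition coefficient K_POM
#' is conventionally taken from a published log-linear calibration against
#' K_OW. That calibration is an external input to this package, so the
#' default shipped here is a generic SUBSTITUTE relation (slope 0.85,
#' intercept 0.30) chosen to give log K_POM values in the 4.8-7.3 range
#' typical of published POM-water coefficients for PCBs. For quantitative
#' work, supply the literature calibration for your sampler instead.
#'
#' @return A [log_linear_relation()].
#' @export
default_k_pom_relation <- function() {
  log_linear_relation(0.85, 0.30)
}
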
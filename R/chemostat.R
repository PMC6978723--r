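# Chemostat rate-to-yield reconciliation: molar yields, biomass yield, and
# carbon / electron (degree-of-reduction) balance closures, plus batch
# growth-rate estimation.

#' Construct a chemostat record
#'
#' Bundles biomass-specific conversion rates with the culture dilution rate
#' and the assumed biomass elemental composition. At steady state the
#' specific growth rate equals the dilution rate, so the biomass formation
#' rate is derived from D unless an explicit \code{biomass} rate is given in
#' \code{rates}.
#'
#' @param rates Named numeric vector of biomass-specific rates q_i in
#'   mmol (g biomass)^-1 h^-1, negative for consumption. Must include the
#'   substrate with a negative rate.
#' @param D Dilution rate, 1/h.
#' @param substrate_id Compound id of the growth substrate.
#' @param biomass_formula Biomass elemental composition (string or
#'   \code{elemental_formula}); default the standard CH1.8O0.5N0.2 per C-mol.
#' @param registry Compound registry.
#' @return Object of class \code{chemostat_record}.
#' @examples
#' chemostat_record(c(galacturonate = -6.9, acetate = 6.0,
#'                    lactate = 5.2, co2 = 7.2), D = 0.13)
#' @export
chemostat_record <- function(rates, D, substrate_id = "galacturonate",
                             biomass_formula = "CH1.8O0.5N0.2",
                             registry = default_registry()) {
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("rates must be a named vector of compound ids", call. = FALSE)
  if (anyDuplicated(names(rates)))
    stop("duplicated compound in rates", call. = FALSE)
  compound_field(setdiff(names(rates), "biomass"), "id", registry)  # registration check
  if (!substrate_id %in% names(rates))
    stop(sprintf("substrate '%s' missing from rates", substrate_id), call. = FALSE)
  if (!is.numeric(D) || length(D) != 1L || D <= 0)
    stop("dilution rate D must be a single positive number", call. = FALSE)
  if (rates[[substrate_id]] >= 0)
    stop("substrate rate must be negative (consumption)", call. = FALSE)
  structure(list(rates = rates, D = D, substrate_id = substrate_id,
                 biomass_formula = as_formula(biomass_formula)),
            class = "chemostat_record")
}

#' @export
print.chemostat_record <- function(x, ...) {
  cat(sprintf("<chemostat_record> D = %g 1/h, substrate %s\n", x$D, x$substrate_id))
  print(x$rates)
  invisible(x)
}

# biomass formation rate in mC-mol (g biomass)^-1 h^-1
biomass_cmol_rate <- function(rec) {
  if ("biomass" %in% names(rec$rates)) return(rec$rates[["biomass"]])
  f <- rec$biomass_formula
  cmol_mass <- molar_mass(f) / unclass(f)[["C"]]
  rec$D / cmol_mass * 1000
}

#' Molar yields from biomass-specific rates
#'
#' yield_i = q_i / |q_substrate| for every non-substrate compound.
#'
#' @param rec A \code{chemostat_record}.
#' @param digits Decimal places for the reported yields (default 2, the
#'   precision at which chemostat yield tables are conventionally printed);
#'   \code{NULL} for full precision.
#' @return Named numeric vector of mol product (mol substrate)^-1.
#' @export
yields_from_rates <- function(rec, digits = 2) {
  qs <- rec$rates[[rec$substrate_id]]
  if (qs == 0) stop("substrate rate is zero; yields undefined", call. = FALSE)
  y <- rec$rates[setdiff(names(rec$rates), c(rec$substrate_id, "biomass"))] / abs(qs)
  if (!is.null(digits)) y <- round(y, digits)
  y
}

#' Biomass yield on substrate
#'
#' Y_xs = D / (|q_s| * 1e-3 * M_s) in g biomass (g substrate)^-1, using the
#' steady-state identity mu = D.
#'
#' @param rec A \code{chemostat_record}.
#' @param registry Compound registry (for the substrate molar mass; the free
#'   acid by default).
#' @return Biomass yield, g/g.
#' @export
biomass_yield <- function(rec, registry = default_registry()) {
  qs <- abs(rec$rates[[rec$substrate_id]])
  if (qs == 0) stop("substrate rate is zero; biomass yield undefined", call. = FALSE)
  M <- compound_field(rec$substrate_id, "molar_mass", registry)
  rec$D / (qs * 1e-3 * M)
}

balance_recovery <- function(rec, weight, registry) {
  ids <- setdiff(names(rec$rates), c(rec$substrate_id, "biomass"))
  qs <- abs(rec$rates[[rec$substrate_id]])
  w_s <- compound_field(rec$substrate_id, weight, registry)
  w_i <- if (length(ids)) compound_field(ids, weight, registry) else numeric(0)
  f <- rec$biomass_formula
  w_x <- switch(weight,
                carbon = 1,
                gamma = degree_of_reduction(f) / unclass(f)[["C"]])
  qx <- biomass_cmol_rate(rec)
  (sum(rec$rates[ids] * w_i) + qx * w_x) / (qs * w_s)
}

#' Carbon balance closure of a chemostat record
#'
#' Fraction of consumed substrate carbon recovered in products plus biomass,
#' with the biomass formation rate derived from the dilution rate and the
#' biomass C-mol mass.
#'
#' @param rec A \code{chemostat_record}.
#' @param registry Compound registry.
#' @return Carbon recovery fraction.
#' @export
carbon_balance <- function(rec, registry = default_registry()) {
  if (is.null(rec$biomass_formula)) stop("biomass formula required", call. = FALSE)
  balance_recovery(rec, "carbon", registry)
}

#' Electron balance closure of a chemostat record
#'
#' As \code{\link{carbon_balance}} but weighting each rate by the compound's
#' degree of reduction; CO2 contributes zero electrons.
#'
#' @inheritParams carbon_balance
#' @return Electron recovery fraction.
#' @export
electron_balance <- function(rec, registry = default_registry()) {
  if (is.null(rec$biomass_formula)) stop("biomass formula required", call. = FALSE)
  balance_recovery(rec, "gamma", registry)
}

#' Full reconciliation report
#'
#' @param rec A \code{chemostat_record}.
#' @param digits Rounding for yields (see \code{\link{yields_from_rates}}).
#' @param registry Compound registry.
#' @return Object of class \code{reconciliation_report} with \code{yields},
#'   \code{biomass_yield} (g/g), \code{carbon_recovery} and
#'   \code{electron_recovery} (reported at 3 decimals).
#' @export
reconcile <- function(rec, digits = 2, registry = default_registry()) {
  structure(list(D = rec$D,
                 substrate = rec$substrate_id,
                 yields = yields_from_rates(rec, digits = digits),
                 biomass_yield = biomass_yield(rec, registry),
                 carbon_recovery = round(carbon_balance(rec, registry), 3),
                 electron_recovery = round(electron_balance(rec, registry), 3)),
            class = "reconciliation_report")
}

#' @export
print.reconciliation_report <- function(x, ...) {
  cat(sprintf("<reconciliation_report> D = %g 1/h, substrate %s\n", x$D, x$substrate))
  cat("  yields [mol/mol]:",
      paste(names(x$yields), x$yields, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  biomass yield: %.3f g/g\n", x$biomass_yield))
  cat(sprintf("  carbon recovery: %.3f, electron recovery: %.3f\n",
              x$carbon_recovery, x$electron_recovery))
  invisible(x)
}

#' Specific growth rate from a batch time course
#'
#' Least-squares slope of ln(OD) versus time over a user-chosen window of
#' the exponential phase.
#'
#' @param tc Data frame with columns \code{time} (h, strictly increasing) and
#'   \code{od} (optical density or biomass, positive), as produced by
#'   \code{\link{gen_batch}}.
#' @param window Numeric length-2 time interval (h) over which to fit.
#' @return List with \code{mu} (1/h), \code{se} (standard error of the
#'   slope), and \code{n} points used.
#' @export
estimate_mu_batch <- function(tc, window = range(tc$time)) {
  if (!all(c("time", "od") %in% names(tc)))
    stop("time course needs columns 'time' and 'od'", call. = FALSE)
  if (is.unsorted(tc$time, strictly = TRUE))
    stop("time must be strictly increasing", call. = FALSE)
  sel <- tc$time >= window[1] & tc$time <= window[2]
  if (sum(sel) < 3) stop("need at least 3 points in the window", call. = FALSE)
  if (any(tc$od[sel] <= 0))
    stop("non-positive OD in window; cannot take log", call. = FALSE)
  fit <- stats::lm(log(od) ~ time, data = tc[sel, ])
  co <- summary(fit)$coefficients
  list(mu = unname(co["time", "Estimate"]), se = unname(co["time", "Std. Error"]),
       n = sum(sel))
}
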
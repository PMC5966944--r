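#' Estimate the specific growth rate
#'
#' The specific growth rate mu (day^-1) is the biomass production rate per
#' unit biomass. During balanced exponential growth ln(biomass) is linear in
#' time, so mu is estimated as the slope of a log-linear least-squares fit
#' over a window of timepoints ending at the evaluation day (default: all
#' timepoints up to and including `day`).
#'
#' @param measurements a [measurement_set()].
#' @param day evaluation day (must be one of the timepoints).
#' @param window timepoints to fit over; default all timepoints `<= day`.
#' @return list of class `vf_growth`: `mu` (day^-1), `day`, `window`,
#'   `fit_r2` (NA-flagged when the fit is degenerate, e.g. constant
#'   biomass).
#' @export
estimate_growth_rate <- function(measurements, day, window = NULL) {
  stopifnot(inherits(measurements, "vf_measurements"))
  tp <- measurements$timepoints
  if (!day %in% tp) vf_stop("day %g is not a measured timepoint", day)
  window <- window %||% tp[tp <= day]
  if (!all(window %in% tp))
    vf_stop("window contains unmeasured timepoints: %s",
            paste(setdiff(window, tp), collapse = ", "))
  if (length(window) < 2L)
    vf_stop("growth-rate window needs at least 2 timepoints")
  idx <- match(window, tp)
  x <- measurements$biomass[idx]
  if (any(x <= 0)) vf_stop("non-positive biomass in growth window")
  fit <- stats::lm(log(x) ~ window)
  mu <- unname(stats::coef(fit)[2])
  r2 <- if (stats::sd(log(x)) == 0) NA_real_   # flat series: R^2 undefined
        else suppressWarnings(summary(fit)$r.squared)
  if (!is.na(r2) && !is.finite(r2)) r2 <- NA_real_
  structure(list(mu = mu, day = day, window = window, fit_r2 = r2),
            class = "vf_growth")
}

#' @export
print.vf_growth <- function(x, ...) {
  cat(sprintf("Specific growth rate at day %g: mu = %.4g day^-1 (log-linear fit over days %s, R^2 = %s)\n",
              x$day, x$mu, paste(x$window, collapse = ","),
              if (is.na(x$fit_r2)) "NA" else sprintf("%.4f", x$fit_r2)))
  invisible(x)
}

#' Convert an accumulated concentration to an exchange flux
#'
#' At steady state over the culture interval, a component accumulating in
#' proportion to biomass corresponds to the exchange flux
#' `v = c * mu`, with `c` in mmol gDW^-1 (mass-based concentrations are
#' first divided by the molar mass, mg gDW^-1 -> mmol gDW^-1).
#'
#' @param concentration measured concentration (>= 0).
#' @param unit `"mmol_per_gDW"` or `"mg_per_gDW"`.
#' @param molar_mass g mol^-1; required for mass-based units.
#' @param growth a `vf_growth` (or a bare mu in day^-1).
#' @return flux in mmol gDW^-1 day^-1.
#' @export
accumulation_flux <- function(concentration, unit = c("mmol_per_gDW", "mg_per_gDW"),
                              molar_mass = NULL, growth) {
  unit <- match.arg(unit)
  if (concentration < 0) vf_stop("concentration must be >= 0")
  mu <- if (inherits(growth, "vf_growth")) growth$mu else growth
  if (!is_scalar_number(mu)) vf_stop("growth must supply a finite mu")
  c_mmol <- if (unit == "mg_per_gDW") {
    if (is.null(molar_mass) || !is_scalar_number(molar_mass) || molar_mass <= 0)
      vf_stop("molar_mass (> 0) required for mass-based concentrations")
    concentration / molar_mass
  } else concentration
  c_mmol * mu
}

#' Convert a respiration measurement to an ATP synthesis rate
#'
#' Oxygen-uptake measurements are commonly reported as nmol O2 min^-1 per g
#' fresh weight. The conversion to an oxidative-phosphorylation ATP rate in
#' mmol gDW^-1 day^-1 needs the fresh-to-dry weight ratio and an assumed
#' ATP yield per oxygen atom (P/O ratio); both must be supplied explicitly.
#'
#' @param o2_rate nmol O2 min^-1 gFW^-1.
#' @param fw_dw_ratio g FW per g DW of the cells.
#' @param atp_per_o ATP synthesised per O atom reduced (P/O).
#' @return ATP synthesis rate, mmol gDW^-1 day^-1.
#' @export
atp_rate_from_o2 <- function(o2_rate, fw_dw_ratio, atp_per_o) {
  if (o2_rate < 0 || fw_dw_ratio <= 0 || atp_per_o <= 0)
    vf_stop("o2_rate >= 0 and positive fw_dw_ratio, atp_per_o required")
  # nmol O2/min/gFW -> mmol O2/day/gDW, then 2 O atoms per O2
  o2_rate * 1440 * 1e-6 * fw_dw_ratio * 2 * atp_per_o
}
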
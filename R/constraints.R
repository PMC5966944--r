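#' Assemble a flux problem from measurements
#'
#' Converts a measurement set into the bound and coupling constraints of a
#' solvable [flux_problem()]:
#' * irreversible reactions get lower bound 0;
#' * each reaction with a measured enzyme capacity gets upper bound equal to
#'   the capacity, and lower bound minus the capacity when reversible;
#' * bounds without capacity information are infinite markers;
#' * every measured component is converted with [accumulation_flux()] and
#'   fixes its mapped reaction as both lower and upper bound;
#' * when the ATP synthesis rate is available, one coupling row constrains
#'   `Vnrj1 + Vnrj2` to the measured respiration value — as a hard equality
#'   by default, or as `mean +/- se` with `respiration_mode = "interval"`.
#'
#' @param network a `vf_network`.
#' @param measurements a [measurement_set()].
#' @param day evaluation day; component values measured at this day are
#'   used, and the default growth window ends here.
#' @param component_map named character vector mapping component ids to
#'   reaction ids; unmapped components must already be reaction ids.
#' @param growth optional `vf_growth`; default estimated from the biomass
#'   series with [estimate_growth_rate()] at `day`.
#' @param respiration_mode `"equality"` (default; measured mean as hard
#'   equality) or `"interval"` (mean +/- `respiration_se`).
#' @param respiration_se standard error for the interval mode.
#' @param respiration_reactions the oxidative-phosphorylation reactions
#'   whose summed flux the respiration measurement constrains.
#' @return a `vf_problem`; its `meta` attribute records the growth estimate
#'   and the fixed exchange values.
#' @export
assemble_problem <- function(network, measurements, day,
                             component_map = NULL, growth = NULL,
                             respiration_mode = c("equality", "interval"),
                             respiration_se = NA_real_,
                             respiration_reactions = c("Vnrj1", "Vnrj2")) {
  respiration_mode <- match.arg(respiration_mode)
  validate_network(network)
  stopifnot(inherits(measurements, "vf_measurements"))
  ids <- reaction_ids(network)
  revs <- vapply(network$reactions, `[[`, TRUE, "reversible")
  caps <- vapply(network$reactions, `[[`, 1, "capacity")

  # (i) directionality; (iii) infinity markers elsewhere
  lb <- ifelse(revs, -Inf, 0)
  ub <- rep(Inf, length(ids))

  # (ii) measured enzyme capacities: network-curated then measurement-set
  meas_caps <- measurements$capacities
  if (length(meas_caps)) {
    unknown <- setdiff(names(meas_caps), ids)
    if (length(unknown))
      vf_stop("capacities reference unknown reaction(s): %s",
              paste(unknown, collapse = ", "))
    caps[match(names(meas_caps), ids)] <- as.numeric(meas_caps)
  }
  has_cap <- !is.na(caps)
  ub[has_cap] <- caps[has_cap]
  lb[has_cap & revs] <- -caps[has_cap & revs]

  growth <- growth %||% estimate_growth_rate(measurements, day)

  # (iv) measured accumulation fluxes fix lb = ub
  comp <- measurements$components
  comp <- comp[comp$day == day, , drop = FALSE]
  fixed_values <- numeric(0)
  if (nrow(comp)) {
    target <- comp$component_id
    if (!is.null(component_map)) {
      mapped <- component_map[target]
      target <- ifelse(is.na(mapped), target, mapped)
    }
    unmatched <- setdiff(target, ids)
    if (length(unmatched))
      vf_stop("measured component(s) with no matching reaction: %s",
              paste(unique(unmatched), collapse = ", "))
    for (k in seq_len(nrow(comp))) {
      fl <- accumulation_flux(comp$value[k], comp$unit[k],
                              if (is.na(comp$molar_mass[k])) NULL else comp$molar_mass[k],
                              growth)
      j <- match(target[k], ids)
      if (is.finite(ub[j]) && fl > ub[j] || fl < ifelse(is.finite(lb[j]), lb[j], -Inf))
        vf_stop("contradictory bounds for reaction '%s': measured flux %.4g outside [%g, %g]",
                ids[j], fl, lb[j], ub[j])
      lb[j] <- ub[j] <- fl
      fixed_values[ids[j]] <- fl
    }
  }

  # (v) respiration coupling on the summed oxidative-phosphorylation rate
  couplings <- NULL
  if (!is.na(measurements$atp_synthesis_rate)) {
    missing_rx <- setdiff(respiration_reactions, ids)
    if (length(missing_rx))
      vf_stop("respiration coupling references unknown reaction(s): %s",
              paste(missing_rx, collapse = ", "))
    a <- as.numeric(ids %in% respiration_reactions)
    R <- measurements$atp_synthesis_rate
    if (respiration_mode == "interval") {
      if (!is_scalar_number(respiration_se) || respiration_se < 0)
        vf_stop("respiration_mode='interval' needs a non-negative respiration_se")
      couplings <- list(A = matrix(a, 1), lower = R - respiration_se,
                        upper = R + respiration_se, labels = "respiration_atp")
    } else {
      couplings <- list(A = matrix(a, 1), lower = R, upper = R,
                        labels = "respiration_atp")
    }
  }

  pr <- flux_problem(build_matrix(network), lb, ub, ids, couplings = couplings)
  attr(pr, "meta") <- list(growth = growth, fixed_values = fixed_values,
                           condition = measurements$condition, day = day)
  pr
}

#' Fraction of dry biomass covered by the measured components
#'
#' Sums the measured component masses (g per g DW) at the stated day and
#' reports the percentage of 1 g DW they account for; the complement is the
#' unmeasured remainder of the biomass.
#'
#' @param measurements a [measurement_set()].
#' @param day evaluation day.
#' @return percentage (0-100+).
#' @export
biomass_coverage <- function(measurements, day) {
  stopifnot(inherits(measurements, "vf_measurements"))
  comp <- measurements$components
  comp <- comp[comp$day == day, , drop = FALSE]
  if (!nrow(comp)) return(0)
  mass_g <- ifelse(comp$unit == "mg_per_gDW", comp$value / 1000,
                   comp$value * comp$molar_mass / 1000)
  if (any(!is.finite(mass_g)))
    vf_stop("component masses not convertible to g/gDW (molar_mass missing for a molar unit?)")
  if (any(mass_g < 0)) vf_stop("negative component mass")
  100 * sum(mass_g)
}
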
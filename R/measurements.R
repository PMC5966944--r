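#' Construct a measurement set
#'
#' The experimental inputs of a flux problem for one culture condition: the
#' biomass time course, accumulated-component concentrations, measured
#' enzyme capacities and the respiration-derived ATP synthesis rate.
#'
#' @param timepoints days since inoculation, strictly increasing.
#' @param biomass g DW L^-1 at each timepoint, all positive.
#' @param components data.frame with columns `component_id`, `day`, `value`
#'   (concentration per g DW), `unit` (`"mmol_per_gDW"` or `"mg_per_gDW"`)
#'   and `molar_mass` (g mol^-1; required iff the unit is mass-based).
#' @param capacities named numeric vector, reaction id -> maximal rate in
#'   mmol gDW^-1 day^-1; may be empty.
#' @param atp_synthesis_rate respiration-derived ATP synthesis rate,
#'   mmol gDW^-1 day^-1, or `NA` when not measured.
#' @param condition free-text label, e.g. `"N"` (control) or `"N-"` (low
#'   nitrogen).
#' @return a `vf_measurements` object.
#' @export
measurement_set <- function(timepoints, biomass, components = NULL,
                            capacities = numeric(0),
                            atp_synthesis_rate = NA_real_,
                            condition = "") {
  if (length(timepoints) != length(biomass))
    vf_stop("timepoints and biomass must have equal length")
  if (is.unsorted(timepoints, strictly = TRUE))
    vf_stop("timepoints must be strictly increasing")
  if (any(!is.finite(biomass)) || any(biomass <= 0))
    vf_stop("biomass values must be positive")
  if (is.null(components))
    components <- data.frame(component_id = character(0), day = numeric(0),
                             value = numeric(0), unit = character(0),
                             molar_mass = numeric(0), stringsAsFactors = FALSE)
  req <- c("component_id", "day", "value", "unit", "molar_mass")
  if (!all(req %in% names(components)))
    vf_stop("components must have columns: %s", paste(req, collapse = ", "))
  if (any(components$value < 0, na.rm = TRUE))
    vf_stop("component concentrations must be >= 0")
  bad_unit <- setdiff(unique(components$unit), c("mmol_per_gDW", "mg_per_gDW"))
  if (length(bad_unit))
    vf_stop("unknown concentration unit(s): %s", paste(bad_unit, collapse = ", "))
  mass_based <- components$unit == "mg_per_gDW"
  if (any(mass_based & !(is.finite(components$molar_mass) & components$molar_mass > 0)))
    vf_stop("molar_mass (> 0) required for every mass-based (mg_per_gDW) component")
  if (length(capacities)) {
    if (is.null(names(capacities)) || any(!nzchar(names(capacities))))
      vf_stop("capacities must be a named vector (reaction id -> rate)")
    if (any(!is.finite(capacities)) || any(capacities < 0))
      vf_stop("capacities must be finite and >= 0")
  }
  structure(list(timepoints = as.numeric(timepoints),
                 biomass = as.numeric(biomass),
                 components = components, capacities = capacities,
                 atp_synthesis_rate = as.numeric(atp_synthesis_rate),
                 condition = condition),
            class = "vf_measurements")
}

#' @export
print.vf_measurements <- function(x, ...) {
  cat(sprintf("Measurement set ('%s'): %d timepoints (days %s)\n",
              x$condition, length(x$timepoints),
              paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  %d component measurements, %d enzyme capacities, ATP rate %s\n",
              nrow(x$components), length(x$capacities),
              if (is.na(x$atp_synthesis_rate)) "not measured"
              else sprintf("%.3g mmol/gDW/day", x$atp_synthesis_rate)))
  invisible(x)
}

#' Read / write measurement CSV files
#'
#' Long-format measurements CSV with columns
#' `condition,day,component_id,value,unit,molar_mass`. Two reserved
#' component ids carry the non-component series: `biomass` (unit
#' `gDW_per_L`) and `respiration_atp` (unit `mmol_per_gDW_day`, the
#' already-converted ATP synthesis rate). Capacities live in a second CSV
#' `condition,reaction_id,capacity`.
#'
#' @param path measurements CSV path.
#' @param capacities_path optional capacities CSV path.
#' @param condition condition label to extract (default: the only one
#'   present; error if ambiguous).
#' @return a `vf_measurements`.
#' @export
read_measurements <- function(path, capacities_path = NULL, condition = NULL) {
  if (!file.exists(path)) vf_stop("measurements file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("condition", "day", "component_id", "value", "unit", "molar_mass")
  if (!all(req %in% names(d)))
    vf_stop("%s: expected columns %s", path, paste(req, collapse = ","))
  if (is.null(condition)) {
    conds <- unique(d$condition)
    if (length(conds) != 1L)
      vf_stop("multiple conditions in %s (%s); pass `condition`",
              path, paste(conds, collapse = ", "))
    condition <- conds
  }
  d <- d[d$condition == condition, , drop = FALSE]
  if (!nrow(d)) vf_stop("no rows for condition '%s' in %s", condition, path)

  bio <- d[d$component_id == "biomass", , drop = FALSE]
  bio <- bio[order(bio$day), , drop = FALSE]
  resp <- d[d$component_id == "respiration_atp", , drop = FALSE]
  comp <- d[!d$component_id %in% c("biomass", "respiration_atp"), , drop = FALSE]

  caps <- numeric(0)
  if (!is.null(capacities_path)) {
    if (!file.exists(capacities_path))
      vf_stop("capacities file not found: %s", capacities_path)
    k <- utils::read.csv(capacities_path, stringsAsFactors = FALSE)
    if (!all(c("condition", "reaction_id", "capacity") %in% names(k)))
      vf_stop("%s: expected columns condition,reaction_id,capacity", capacities_path)
    k <- k[k$condition == condition, , drop = FALSE]
    caps <- stats::setNames(k$capacity, k$reaction_id)
  }
  measurement_set(
    timepoints = bio$day, biomass = bio$value,
    components = comp[, c("component_id", "day", "value", "unit", "molar_mass")],
    capacities = caps,
    atp_synthesis_rate = if (nrow(resp)) resp$value[1] else NA_real_,
    condition = condition)
}

#' @rdname read_measurements
#' @param measurements a `vf_measurements`.
#' @export
write_measurements <- function(measurements, path, capacities_path = NULL) {
  ms <- measurements
  rows <- data.frame(
    condition = ms$condition, day = ms$timepoints, component_id = "biomass",
    value = ms$biomass, unit = "gDW_per_L", molar_mass = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.na(ms$atp_synthesis_rate))
    rows <- rbind(rows, data.frame(
      condition = ms$condition, day = min(ms$timepoints),
      component_id = "respiration_atp", value = ms$atp_synthesis_rate,
      unit = "mmol_per_gDW_day", molar_mass = NA_real_))
  if (nrow(ms$components))
    rows <- rbind(rows, data.frame(
      condition = ms$condition, day = ms$components$day,
      component_id = ms$components$component_id, value = ms$components$value,
      unit = ms$components$unit, molar_mass = ms$components$molar_mass))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  if (!is.null(capacities_path) && length(ms$capacities)) {
    utils::write.csv(data.frame(condition = ms$condition,
                                reaction_id = names(ms$capacities),
                                capacity = as.numeric(ms$capacities)),
                     capacities_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
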
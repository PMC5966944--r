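#' Create a metabolite
#'
#' A network species. Internal metabolites are mass-balanced at steady state;
#' external metabolites (medium nutrients, vacuolar/accumulated pools, biomass
#' products) sit outside the balance and act as sources or sinks.
#'
#' @param id short unique token, e.g. `"g6p"`.
#' @param name free-text name; defaults to `id`.
#' @param role `"internal"` (balanced) or `"external"`.
#' @param compartment informational label (`"cytosol"`, `"vacuole"`,
#'   `"mitochondrion"`, ...). The model pools each species over the whole
#'   cell; the tag is annotation only.
#' @param cofactor logical; marks ATP/ADP/AMP, NAD(H), NADP(H), FAD(H2).
#'   Cofactors must be internal, so that their production and consumption
#'   cancel and redox/energy status constrains the carbon network.
#' @return a `vf_metabolite` list.
#' @export
metabolite <- function(id, name = id, role = c("internal", "external"),
                       compartment = "cytosol", cofactor = FALSE) {
  role <- match.arg(role)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    vf_stop("metabolite id must be a non-empty string")
  if (isTRUE(cofactor) && role != "internal")
    vf_stop("cofactor '%s' must have role 'internal' (cofactors are balanced)", id)
  structure(list(id = id, name = name, role = role,
                 compartment = compartment, cofactor = isTRUE(cofactor)),
            class = "vf_metabolite")
}

#' Create a reaction
#'
#' @param id short unique token (e.g. `"Vpk"`, `"Vac-mal"`).
#' @param stoich named numeric vector: metabolite id -> signed coefficient,
#'   negative for consumption. Stored sorted by metabolite id (canonical
#'   order, so that file round trips are bit-exact).
#' @param reversible logical; irreversible reactions get lower bound 0 when a
#'   flux problem is assembled.
#' @param kind `"internal"` (enzymatic step), `"exchange"` (uptake or simple
#'   accumulation, touches at least one external metabolite), `"overall"`
#'   (lumped biosynthesis of a biomass/phenolic product) or `"maintenance"`
#'   (non-growth ATP hydrolysis).
#' @param capacity optional maximal rate in mmol gDW^-1 day^-1 (measured
#'   enzyme capacity); `NA` means unconstrained.
#' @param name free-text name.
#' @return a `vf_reaction` list.
#' @export
reaction <- function(id, stoich, reversible = FALSE,
                     kind = c("internal", "exchange", "overall", "maintenance"),
                     capacity = NA_real_, name = id) {
  kind <- match.arg(kind)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    vf_stop("reaction id must be a non-empty string")
  if (length(stoich) == 0L || is.null(names(stoich)) || any(!nzchar(names(stoich))))
    vf_stop("reaction '%s': stoichiometry must be a non-empty named vector", id)
  if (anyDuplicated(names(stoich)))
    vf_stop("reaction '%s': duplicated metabolite in stoichiometry", id)
  if (!all(is.finite(stoich)) || any(stoich == 0))
    vf_stop("reaction '%s': coefficients must be finite and non-zero", id)
  if (!is.na(capacity) && capacity < 0)
    vf_stop("reaction '%s': capacity must be >= 0", id)
  stoich <- stoich[order(names(stoich))]
  structure(list(id = id, name = name, kind = kind,
                 reversible = isTRUE(reversible),
                 capacity = as.numeric(capacity), stoich = stoich),
            class = "vf_reaction")
}

#' Assemble a stoichiometric network
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions ordered list of [reaction()] objects; the order fixes the
#'   indexing of flux vectors.
#' @param provenance free-text version note.
#' @param validate run [validate_network()] (default `TRUE`).
#' @return a `vf_network` object.
#' @export
stoichiometric_network <- function(metabolites, reactions,
                                   provenance = "", validate = TRUE) {
  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        provenance = provenance),
                   class = "vf_network")
  if (validate) validate_network(net)
  net
}

#' Validate network invariants
#'
#' Checks id uniqueness, referenced metabolites, role constraints, exchange
#' reactions touching an external species, and non-negative capacities.
#'
#' @param network a `vf_network`.
#' @return the network, invisibly; errors on violation.
#' @export
validate_network <- function(network) {
  if (!inherits(network, "vf_network")) vf_stop("not a vf_network")
  mids <- metabolite_ids(network)
  rids <- reaction_ids(network)
  if (length(mids) == 0L || length(rids) == 0L)
    vf_stop("network must contain at least one metabolite and one reaction")
  if (anyDuplicated(mids))
    vf_stop("duplicated metabolite id(s): %s",
            paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (anyDuplicated(rids))
    vf_stop("duplicated reaction id(s): %s",
            paste(unique(rids[duplicated(rids)]), collapse = ", "))
  roles <- vapply(network$metabolites, `[[`, "", "role")
  if (!any(roles == "internal"))
    vf_stop("network has no internal metabolite")
  ext <- mids[roles == "external"]
  for (r in network$reactions) {
    unknown <- setdiff(names(r$stoich), mids)
    if (length(unknown))
      vf_stop("reaction '%s' references unknown metabolite(s): %s",
              r$id, paste(unknown, collapse = ", "))
    if (r$kind == "exchange" && !any(names(r$stoich) %in% ext))
      vf_stop("exchange reaction '%s' touches no external metabolite", r$id)
  }
  invisible(network)
}

#' @export
print.vf_network <- function(x, ...) {
  roles <- vapply(x$metabolites, `[[`, "", "role")
  kinds <- vapply(x$reactions, `[[`, "", "kind")
  irr_int <- sum(!vapply(x$reactions, `[[`, TRUE, "reversible") & kinds == "internal")
  cat(sprintf("Stoichiometric network: %d metabolites (%d internal), %d reactions\n",
              length(x$metabolites), sum(roles == "internal"), length(x$reactions)))
  cat(sprintf("  kinds: %s\n",
              paste(sprintf("%s=%d", names(table(kinds)), table(kinds)), collapse = ", ")))
  cat(sprintf("  irreversible internal reactions: %d\n", irr_int))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Metabolite / reaction accessors
#'
#' @param network a `vf_network`.
#' @return character vector of ids, in network order.
#' @export
metabolite_ids <- function(network) vapply(network$metabolites, `[[`, "", "id")

#' @rdname metabolite_ids
#' @export
reaction_ids <- function(network) vapply(network$reactions, `[[`, "", "id")

#' @rdname metabolite_ids
#' @export
internal_metabolite_ids <- function(network) {
  roles <- vapply(network$metabolites, `[[`, "", "role")
  metabolite_ids(network)[roles == "internal"]
}

#' Summary table of the reactions of a network
#'
#' @param network a `vf_network`.
#' @return data.frame with id, kind, reversible, capacity and a printable
#'   equation string, one row per reaction in network order.
#' @export
reaction_table <- function(network) {
  data.frame(
    id = reaction_ids(network),
    kind = vapply(network$reactions, `[[`, "", "kind"),
    reversible = vapply(network$reactions, `[[`, TRUE, "reversible"),
    capacity = vapply(network$reactions, `[[`, 1, "capacity"),
    equation = vapply(network$reactions, reaction_equation, ""),
    stringsAsFactors = FALSE
  )
}

reaction_equation <- function(r) {
  lhs <- r$stoich[r$stoich < 0]
  rhs <- r$stoich[r$stoich > 0]
  fmt <- function(s) paste(ifelse(abs(s) == 1, names(s),
                                  paste0(abs(s), " ", names(s))), collapse = " + ")
  paste(fmt(lhs), if (r$reversible) "<->" else "->", fmt(rhs))
}

#' Count irreversible internal reactions
#'
#' The reconstruction's directionality is summarised, as in the source
#' network description, by the number of one-directional *internal* steps;
#' exchange, overall and maintenance reactions are one-directional sinks or
#' sources by construction and are not part of this count.
#'
#' @param network a `vf_network`.
#' @return integer count.
#' @export
count_irreversible_internal <- function(network) {
  kinds <- vapply(network$reactions, `[[`, "", "kind")
  revs <- vapply(network$reactions, `[[`, TRUE, "reversible")
  sum(kinds == "internal" & !revs)
}
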
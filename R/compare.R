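#' Relative flux changes between two conditions
#'
#' Per-reaction percent change `100 * (v_t - v_c) / |v_c|` between a control
#' and a treatment solution over the same network. Entries whose control
#' flux is numerically zero (`|v_c| < eps`) are flagged undefined rather
#' than reported as infinite, and sign reversals are flagged separately
#' since a percentage does not express them faithfully. Reactions are
#' classified `increased` / `decreased` / `unchanged` against a dead-band.
#'
#' @param control,treatment `vf_solution`s with identical reaction
#'   ordering.
#' @param network the `vf_network` both were solved on (adds the reaction
#'   kind to the output).
#' @param dead_band half-width of the "unchanged" band in percent (default
#'   5).
#' @param eps control-flux magnitude below which the change is undefined
#'   (default `1e-9`).
#' @param labels length-2 condition labels.
#' @param day evaluation day (annotation only).
#' @return data.frame of class `vf_comparison`: `reaction_id`, `kind`,
#'   `flux_control`, `flux_treatment`, `percent_change`, `sign_flip`,
#'   `class`.
#' @export
percent_change_map <- function(control, treatment, network = NULL,
                               dead_band = 5, eps = 1e-9,
                               labels = c("control", "treatment"),
                               day = NA_real_) {
  if (!identical(names(control$v), names(treatment$v)))
    vf_stop("control and treatment solutions have mismatched reaction sets")
  vc <- as.numeric(control$v); vt <- as.numeric(treatment$v)
  defined <- abs(vc) >= eps
  pc <- rep(NA_real_, length(vc))
  pc[defined] <- 100 * (vt[defined] - vc[defined]) / abs(vc[defined])
  cls <- ifelse(!defined, "undefined",
         ifelse(pc > dead_band, "increased",
         ifelse(pc < -dead_band, "decreased", "unchanged")))
  out <- data.frame(
    reaction_id = names(control$v),
    kind = if (is.null(network)) NA_character_
           else vapply(network$reactions, `[[`, "", "kind"),
    flux_control = vc, flux_treatment = vt,
    percent_change = pc,
    sign_flip = defined & abs(vt) >= eps & sign(vc) != sign(vt),
    class = cls, stringsAsFactors = FALSE)
  attr(out, "labels") <- labels
  attr(out, "day") <- day
  attr(out, "dead_band") <- dead_band
  class(out) <- c("vf_comparison", "data.frame")
  out
}

#' Cofactor production/consumption ledger
#'
#' Decomposes the turnover of a balanced cofactor at a flux solution:
#' each reaction contributes `stoichiometric coefficient x flux`. Because
#' cofactors are internal (balanced) metabolites, total production and
#' total consumption cancel at any mass-balanced solution — the ledger
#' shows *which* reactions carry the energy or redox load.
#'
#' @param network a `vf_network`.
#' @param solution a `vf_solution`.
#' @param cofactor_id metabolite id flagged as cofactor (e.g. `"atp"`,
#'   `"nadph"`).
#' @return list of class `vf_ledger`: `cofactor`, `contributions`
#'   (data.frame sorted by |contribution|), `production`, `consumption`,
#'   `net`.
#' @export
cofactor_ledger <- function(network, solution, cofactor_id) {
  validate_network(network)
  mids <- metabolite_ids(network)
  if (!cofactor_id %in% mids) vf_stop("unknown metabolite id '%s'", cofactor_id)
  met <- network$metabolites[[match(cofactor_id, mids)]]
  if (!met$cofactor)
    vf_stop("metabolite '%s' is not flagged as a cofactor", cofactor_id)
  ledger_core(network, solution, cofactor_id)
}

# shared by cofactor_ledger and metabolite-level audits
ledger_core <- function(network, solution, met_id) {
  coefs <- vapply(network$reactions, function(r) {
    if (met_id %in% names(r$stoich)) r$stoich[[met_id]] else 0
  }, 1)
  v <- as.numeric(solution$v)
  contrib <- coefs * v
  keep <- coefs != 0
  df <- data.frame(reaction_id = reaction_ids(network)[keep],
                   coefficient = coefs[keep], flux = v[keep],
                   contribution = contrib[keep], stringsAsFactors = FALSE)
  df <- df[order(-abs(df$contribution)), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(cofactor = met_id, contributions = df,
                 production = sum(contrib[contrib > 0]),
                 consumption = sum(contrib[contrib < 0]),
                 net = sum(contrib)),
            class = "vf_ledger")
}

#' @export
print.vf_ledger <- function(x, n = 8, ...) {
  cat(sprintf("%s ledger: production %.4g, consumption %.4g, net %.3g (mmol/gDW/day)\n",
              x$cofactor, x$production, x$consumption, x$net))
  print(utils::head(x$contributions, n))
  invisible(x)
}

#' 2-oxoglutarate branch-point summary
#'
#' Lists every reaction consuming 2-oxoglutarate (alpha-ketoglutarate) at
#' the given solution, with its flux-weighted consumption and its share of
#' the total. The branch point distributes carbon between the TCA cycle
#' (`Vkgdh`), nitrogen assimilation (`Vgogat`, transaminases) and the
#' 2-OG-dependent dioxygenases of the flavonoid pathway (`Vdhq`, `Vflav`,
#' `Vanthoc`), which is what makes it the crossroads between growth and
#' polyphenol production.
#'
#' @param network a `vf_network` containing the metabolite `akg_id`.
#' @param solution a `vf_solution`.
#' @param akg_id metabolite id of 2-oxoglutarate (default `"akg"`).
#' @return data.frame: `reaction_id`, `coefficient`, `flux`, `consumption`
#'   (positive mmol gDW^-1 day^-1) and `share` (fraction of the total,
#'   summing to 1 when total consumption > 0).
#' @export
akg_branch_summary <- function(network, solution, akg_id = "akg") {
  mids <- metabolite_ids(network)
  if (!akg_id %in% mids)
    vf_stop("2-oxoglutarate ('%s') absent from the network", akg_id)
  roles <- vapply(network$metabolites, `[[`, "", "role")
  if (roles[match(akg_id, mids)] != "internal")
    vf_stop("'%s' must be an internal metabolite", akg_id)
  led <- ledger_core(network, solution, akg_id)
  df <- led$contributions
  # consumption in the realised direction: negative contribution entries
  df <- df[df$contribution < 0, , drop = FALSE]
  df$consumption <- -df$contribution
  df$contribution <- NULL
  total <- sum(df$consumption)
  df$share <- if (total > 0) df$consumption / total else NA_real_
  df <- df[order(-df$consumption), , drop = FALSE]
  rownames(df) <- NULL
  df
}
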
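#' Build the stoichiometric matrix
#'
#' Assembles the dense matrix N of the steady-state mass balance N v = 0:
#' one row per internal metabolite (network order), one column per reaction
#' (network order). External metabolites contribute no row, which is what
#' makes them unbalanced sources/sinks.
#'
#' @param network a validated `vf_network`.
#' @return numeric matrix with dimnames (internal metabolite ids x reaction
#'   ids). A network whose metabolites are all external yields a 0-row
#'   matrix.
#' @export
build_matrix <- function(network) {
  validate_network(network)
  int <- internal_metabolite_ids(network)
  rids <- reaction_ids(network)
  S <- matrix(0, nrow = length(int), ncol = length(rids),
              dimnames = list(int, rids))
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoich
    keep <- names(st) %in% int
    if (any(keep)) S[names(st)[keep], j] <- st[keep]
  }
  S
}

#' Full coefficient matrix including external species
#'
#' Like [build_matrix()] but with one row per metabolite regardless of role.
#' Used for ledgers and graph export, never for the mass balance.
#'
#' @param network a `vf_network`.
#' @return numeric matrix (all metabolite ids x reaction ids).
#' @export
build_full_matrix <- function(network) {
  mids <- metabolite_ids(network)
  rids <- reaction_ids(network)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}
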
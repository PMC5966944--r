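#' Stoichiometric consistency report
#'
#' A network is stoichiometrically consistent when every internal metabolite
#' can be assigned a strictly positive molecular weight such that every
#' non-exchange, non-overall reaction (i.e. the actual enzymatic chemistry
#' plus maintenance) conserves total weight. Inconsistency reveals
#' mass-creating or mass-destroying stoichiometry (e.g. an autocatalytic
#' `A -> 2A`). Exchange and overall reactions legitimately move mass across
#' the system boundary and are excluded.
#'
#' The weight search is solved as a box-constrained least-squares problem
#' (minimise \eqn{\|B^T w\|^2} subject to \eqn{w \ge 1}, with `B` the
#' internal-reaction block of the stoichiometric matrix) via L-BFGS-B; the
#' network is conserved iff the minimum is numerically zero.
#'
#' @param network a `vf_network`.
#' @param tol relative tolerance on the residual norm.
#' @return a list of class `vf_consistency`: `conserved` (logical),
#'   `weights` (named, only meaningful when conserved), `residual`,
#'   `orphan_metabolites` (internal metabolites appearing in no reaction),
#'   `dead_end_metabolites` (internal metabolites only ever produced or only
#'   ever consumed, counting both directions of reversible reactions).
#' @export
check_consistency <- function(network, tol = 1e-6) {
  validate_network(network)
  S <- build_matrix(network)
  kinds <- vapply(network$reactions, `[[`, "", "kind")
  B <- S[, kinds %in% c("internal", "maintenance"), drop = FALSE]

  m <- nrow(S)
  if (ncol(B) == 0L) {
    conserved <- TRUE; w <- rep(1, m); resid <- 0
  } else {
    obj <- function(w) sum((crossprod(B, w))^2)
    grad <- function(w) as.numeric(2 * B %*% crossprod(B, w))
    fit <- stats::optim(rep(1, m), obj, grad, method = "L-BFGS-B",
                        lower = rep(1, m), upper = rep(1e6, m),
                        control = list(maxit = 2000, factr = 1e3))
    w <- fit$par
    resid <- sqrt(fit$value) / (1 + sqrt(sum(w^2)))
    conserved <- resid <= tol
  }
  names(w) <- rownames(S)

  in_any <- rowSums(S != 0) > 0
  orphans <- rownames(S)[!in_any]

  # a reversible reaction can both produce and consume each participant
  revs <- vapply(network$reactions, `[[`, TRUE, "reversible")
  can_produce <- rowSums(S > 0 | (S != 0 & rep(revs, each = nrow(S)))) > 0
  can_consume <- rowSums(S < 0 | (S != 0 & rep(revs, each = nrow(S)))) > 0
  dead <- rownames(S)[in_any & xor(can_produce, can_consume)]

  structure(list(conserved = conserved, weights = w, residual = resid,
                 orphan_metabolites = orphans, dead_end_metabolites = dead),
            class = "vf_consistency")
}

#' @export
print.vf_consistency <- function(x, ...) {
  cat(sprintf("Stoichiometric consistency: %s (residual %.3g)\n",
              if (x$conserved) "conserved" else "NOT conserved", x$residual))
  cat(sprintf("  orphan internal metabolites: %s\n",
              if (length(x$orphan_metabolites)) paste(x$orphan_metabolites, collapse = ", ") else "none"))
  cat(sprintf("  dead-end internal metabolites: %s\n",
              if (length(x$dead_end_metabolites)) paste(x$dead_end_metabolites, collapse = ", ") else "none"))
  invisible(x)
}
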
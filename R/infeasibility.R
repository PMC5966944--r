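#' Diagnose an infeasible flux problem
#'
#' Solves an elastic relaxation: every fixed exchange flux (`lb == ub`) and
#' every coupling row receives a slack variable, the mass balance and the
#' remaining bounds stay hard, and the total squared slack (plus a tiny
#' ridge on the fluxes, to keep the program strictly convex) is minimised.
#' Constraints that need a non-zero slack are exactly the measurements that
#' cannot be honoured simultaneously; they are reported ranked by the
#' magnitude of the required relaxation.
#'
#' @param problem a `vf_problem` (typically one for which [minimize_flux()]
#'   returned `"infeasible"`).
#' @param slack_tol slacks below this are reported as zero (default `1e-7`).
#' @param ridge weight of the flux ridge term (default `1e-8`).
#' @param big_m cap for infinite bounds, as in [minimize_flux()].
#' @return data.frame of class `vf_relaxation` with columns `constraint`,
#'   `type` (`"fixed_exchange"` or `"coupling"`), `target`, `relaxed_to`,
#'   `slack`, sorted by `abs(slack)` decreasing; zero rows when the problem
#'   is feasible as given. Errors if even the elastic problem is infeasible
#'   (structurally inconsistent hard constraints).
#' @export
diagnose_infeasibility <- function(problem, slack_tol = 1e-7, ridge = 1e-8,
                                   big_m = 1e6) {
  stopifnot(inherits(problem, "vf_problem"))
  n <- ncol(problem$S)
  ids <- problem$reaction_ids
  fixed <- which(problem$lb == problem$ub)
  ncp <- if (is.null(problem$couplings)) 0L else nrow(problem$couplings$A)
  ns <- length(fixed) + ncp
  if (ns == 0L) {
    sol <- minimize_flux(problem, big_m = big_m)
    if (sol$status == "optimal") return(empty_relaxation())
    vf_stop("problem is infeasible but has no fixed exchange or coupling row to relax")
  }

  # augmented variables x = (v, s)
  S_aug <- cbind(problem$S, matrix(0, nrow(problem$S), ns))
  rows <- list(); rhs <- c(); lab <- c(); typ <- c(); tgt <- c()
  for (k in seq_along(fixed)) {
    r <- numeric(n + ns); r[fixed[k]] <- 1; r[n + k] <- -1
    rows[[length(rows) + 1L]] <- r
    rhs <- c(rhs, problem$lb[fixed[k]])
    lab <- c(lab, ids[fixed[k]]); typ <- c(typ, "fixed_exchange")
    tgt <- c(tgt, problem$lb[fixed[k]])
  }
  if (ncp) {
    cp <- problem$couplings
    for (k in seq_len(ncp)) {
      # elasticise at the midpoint for interval rows, at the rhs for equalities
      mid <- if (is.finite(cp$lower[k]) && is.finite(cp$upper[k]))
        (cp$lower[k] + cp$upper[k]) / 2 else (if (is.finite(cp$lower[k])) cp$lower[k] else cp$upper[k])
      r <- numeric(n + ns); r[seq_len(n)] <- cp$A[k, ]; r[n + length(fixed) + k] <- -1
      rows[[length(rows) + 1L]] <- r
      rhs <- c(rhs, mid)
      lab <- c(lab, cp$labels[k]); typ <- c(typ, "coupling")
      tgt <- c(tgt, mid)
    }
  }
  A_el <- do.call(rbind, rows)

  lb2 <- problem$lb; ub2 <- problem$ub
  lb2[fixed] <- -Inf; ub2[fixed] <- Inf
  elastic <- flux_problem(
    S = cbind(S_aug),
    lb = c(lb2, rep(-Inf, ns)), ub = c(ub2, rep(Inf, ns)),
    reaction_ids = c(ids, paste0(".slack_", lab)),
    couplings = list(A = A_el, lower = rhs, upper = rhs, labels = lab),
    weights = c(rep(ridge, n), rep(1, ns)))
  sol <- minimize_flux(elastic, big_m = big_m)
  if (sol$status != "optimal")
    vf_stop("elastic relaxation itself infeasible: hard bounds and mass balance are inconsistent")

  s <- as.numeric(sol$v[n + seq_len(ns)])
  out <- data.frame(constraint = lab, type = typ, target = tgt,
                    relaxed_to = tgt + ifelse(abs(s) > slack_tol, s, 0),
                    slack = ifelse(abs(s) > slack_tol, s, 0),
                    stringsAsFactors = FALSE)
  out <- out[abs(out$slack) > 0, , drop = FALSE]
  out <- out[order(-abs(out$slack)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vf_relaxation", "data.frame")
  out
}

empty_relaxation <- function() {
  structure(data.frame(constraint = character(0), type = character(0),
                       target = numeric(0), relaxed_to = numeric(0),
                       slack = numeric(0), stringsAsFactors = FALSE),
            class = c("vf_relaxation", "data.frame"))
}
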
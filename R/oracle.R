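#' Exact small-problem oracle by active-set enumeration
#'
#' Independent reference solver for problems with at most 12 reactions.
#' Every combination of bound activations (each flux free, at its finite
#' lower bound, or at its finite upper bound) is enumerated; for each
#' combination the equality-constrained weighted least-norm system is solved
#' in closed form through an SVD pseudo-inverse, infeasible candidates are
#' discarded, and the feasible candidate with the smallest objective is
#' returned. Shares no code path with [minimize_flux()], which makes it a
#' genuine cross-check of the production solver.
#'
#' @param problem a [flux_problem()] with `ncol(S) <= 12`.
#' @param tol feasibility tolerance.
#' @param max_combos refuse enumeration beyond this many active-set
#'   combinations (default `2e5`).
#' @return a `vf_solution` (status `"optimal"` or `"infeasible"`).
#' @export
solve_oracle_small <- function(problem, tol = 1e-9, max_combos = 2e5) {
  stopifnot(inherits(problem, "vf_problem"))
  n <- ncol(problem$S)
  if (n > 12L) vf_stop("solve_oracle_small refuses problems with > 12 reactions (got %d)", n)
  w <- problem$weights
  lb <- problem$lb; ub <- problem$ub

  Aeq <- problem$S
  beq <- rep(0, nrow(problem$S))
  ineqA <- NULL; ineql <- NULL; inequ <- NULL
  if (!is.null(problem$couplings)) {
    cp <- problem$couplings
    iseq <- cp$lower == cp$upper
    if (any(iseq)) {
      Aeq <- rbind(Aeq, cp$A[iseq, , drop = FALSE])
      beq <- c(beq, cp$lower[iseq])
    }
    if (any(!iseq)) {
      ineqA <- cp$A[!iseq, , drop = FALSE]
      ineql <- cp$lower[!iseq]; inequ <- cp$upper[!iseq]
    }
  }

  # per-flux activation options: 0 free, 1 at lb, 2 at ub
  opts <- vector("list", n)
  for (i in seq_len(n)) {
    if (lb[i] == ub[i]) { opts[[i]] <- 1L; next }
    o <- 0L
    if (is.finite(lb[i])) o <- c(o, 1L)
    if (is.finite(ub[i])) o <- c(o, 2L)
    opts[[i]] <- o
  }
  ncomb <- prod(lengths(opts))
  if (ncomb > max_combos)
    vf_stop("active-set enumeration too large (%g combinations)", ncomb)

  grid <- as.matrix(expand.grid(opts, KEEP.OUT.ATTRS = FALSE))
  best_v <- NULL; best_obj <- Inf
  scale0 <- 1 + max(abs(beq), abs(lb[is.finite(lb)]), abs(ub[is.finite(ub)]), 0)

  for (k in seq_len(nrow(grid))) {
    a <- grid[k, ]
    v <- numeric(n)
    act <- a != 0L
    v[a == 1L] <- lb[a == 1L]
    v[a == 2L] <- ub[a == 2L]
    fre <- which(!act)
    if (length(fre)) {
      Af <- Aeq[, fre, drop = FALSE]
      rhs <- beq - (if (any(act)) Aeq[, act, drop = FALSE] %*% v[act] else 0)
      # weighted least-norm solution on the active-set-constrained subspace
      Winv <- 1 / w[fre]
      G <- Af %*% (Winv * t(Af))
      y <- pinv(G) %*% rhs
      vf <- Winv * as.numeric(crossprod(Af, y))
      if (nrow(Af) && max(abs(Af %*% vf - rhs)) > tol * scale0 * 1e3) next  # inconsistent
      v[fre] <- vf
    } else if (nrow(Aeq) && max(abs(Aeq %*% v - beq)) > 1e-7 * scale0) next
    sc <- rel_scale(v)
    if (any(v < lb - 1e-9 * sc) || any(v > ub + 1e-9 * sc)) next
    if (!is.null(ineqA)) {
      cv <- as.numeric(ineqA %*% v)
      if (any(cv < ineql - 1e-9 * sc) || any(cv > inequ + 1e-9 * sc)) next
    }
    if (nrow(Aeq) && max(abs(Aeq %*% v - beq)) > 1e-7 * sc) next
    obj <- sum(w * v^2)
    if (obj < best_obj - 1e-14) { best_obj <- obj; best_v <- v }
  }

  if (is.null(best_v)) {
    v <- rep(NA_real_, n)
    names(v) <- problem$reaction_ids
    return(structure(list(v = v, objective = NA_real_, status = "infeasible",
                          balance_residual = NA_real_, bound_violation = NA_real_,
                          kkt_residual = NA_real_, at_bound = rep(NA, n),
                          note = "enumeration found no feasible active set",
                          tol = tol, opt_tol = NA_real_),
                     class = "vf_solution"))
  }
  new_solution(problem, best_v, "optimal", tol = 1e-7, opt_tol = 1e-6)
}
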
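#' Solve the quadratic flux-minimization problem
#'
#' Minimises \eqn{\sum_i w_i v_i^2} over the steady-state polytope
#' \eqn{Sv = 0}, coupling rows, and box bounds. The objective is strictly
#' convex, so the optimal flux vector is unique whenever the problem is
#' feasible — the property that makes flux minimization a well-posed
#' resolution of the underdetermined mass balance.
#'
#' Implementation: fixed fluxes (`lb == ub`) are eliminated by substitution,
#' equality rows are rank-reduced by QR, infinite bounds are capped at
#' `big_m`, and the reduced program is handed to the dual active-set method
#' of Goldfarb and Idnani (`quadprog::solve.QP`). The returned active set is
#' then polished by an exact equality-constrained re-solve, which brings the
#' solution to near machine precision (important for scale-equivariance and
#' permutation-invariance guarantees). If any free flux ends within 1% of
#' the artificial `big_m` cap a warning is raised: the cap stood in for an
#' infinite bound and has become binding.
#'
#' @param problem a [flux_problem()].
#' @param tol feasibility tolerance (default `1e-9`), used relative to
#'   `1 + max(abs(v))`.
#' @param opt_tol optimality (stationarity) tolerance, relative (default
#'   `1e-8`).
#' @param big_m finite stand-in for infinite bounds at solver hand-off
#'   (default `1e6` mmol gDW^-1 day^-1).
#' @return a `vf_solution`: fluxes `v` (named), `objective`, `status` one of
#'   `"optimal"`, `"infeasible"`, `"numerical-failure"`, residuals
#'   (`balance_residual`, `bound_violation`, `kkt_residual`), and
#'   `at_bound` flags.
#' @export
minimize_flux <- function(problem, tol = 1e-9, opt_tol = 1e-8, big_m = 1e6) {
  stopifnot(inherits(problem, "vf_problem"))
  n <- ncol(problem$S)
  w <- problem$weights
  lb <- problem$lb; ub <- problem$ub
  ids <- problem$reaction_ids

  # equality block: mass balance + equality couplings
  Aeq <- problem$S
  beq <- rep(0, nrow(problem$S))
  Ail <- NULL; bil <- NULL   # a'v >= l rows
  Aiu <- NULL; biu <- NULL   # a'v <= u rows
  if (!is.null(problem$couplings)) {
    cp <- problem$couplings
    iseq <- cp$lower == cp$upper
    if (any(iseq)) {
      Aeq <- rbind(Aeq, cp$A[iseq, , drop = FALSE])
      beq <- c(beq, cp$lower[iseq])
    }
    lo <- !iseq & is.finite(cp$lower)
    if (any(lo)) { Ail <- cp$A[lo, , drop = FALSE]; bil <- cp$lower[lo] }
    hi <- !iseq & is.finite(cp$upper)
    if (any(hi)) { Aiu <- cp$A[hi, , drop = FALSE]; biu <- cp$upper[hi] }
  }

  fixed <- lb == ub
  vfix <- lb[fixed]
  free <- which(!fixed)

  finish <- function(vfull, status, note = NULL) {
    sol <- new_solution(problem, vfull, status, tol, opt_tol, note)
    sol
  }

  if (length(free) == 0L) {
    v <- numeric(n); v[fixed] <- vfix
    res <- max(abs(Aeq %*% v - beq), 0)
    st <- if (res <= tol * rel_scale(v)) "optimal" else "infeasible"
    return(finish(v, st))
  }

  beq_f <- beq - (if (any(fixed)) Aeq[, fixed, drop = FALSE] %*% vfix else 0)
  Aeq_f <- Aeq[, free, drop = FALSE]

  # rank-reduce the equality rows; dropped rows are re-checked post-solve
  keep <- seq_len(nrow(Aeq_f))
  if (nrow(Aeq_f) > 0L) {
    qa <- qr(t(Aeq_f))
    keep <- sort(qa$pivot[seq_len(qa$rank)])
  }
  Ak <- Aeq_f[keep, , drop = FALSE]
  bk <- beq_f[keep]

  lbf <- pmax(lb[free], -big_m)
  ubf <- pmin(ub[free], big_m)

  Amat <- t(Ak)
  bvec <- bk
  if (!is.null(Ail)) {
    Amat <- cbind(Amat, t(Ail[, free, drop = FALSE]))
    bvec <- c(bvec, bil - (if (any(fixed)) Ail[, fixed, drop = FALSE] %*% vfix else 0))
  }
  if (!is.null(Aiu)) {
    Amat <- cbind(Amat, -t(Aiu[, free, drop = FALSE]))
    bvec <- c(bvec, -(biu - (if (any(fixed)) Aiu[, fixed, drop = FALSE] %*% vfix else 0)))
  }
  nf <- length(free)
  Amat <- cbind(Amat, diag(nf), -diag(nf))
  bvec <- c(bvec, lbf, -ubf)

  fit <- tryCatch(
    quadprog::solve.QP(Dmat = diag(2 * w[free], nf), dvec = rep(0, nf),
                       Amat = Amat, bvec = bvec, meq = nrow(Ak)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    if (grepl("inconsistent|no solution", conditionMessage(fit))) {
      v <- numeric(n); v[fixed] <- vfix; v[free] <- NA_real_
      return(finish(v, "infeasible", note = conditionMessage(fit)))
    }
    v <- numeric(n); v[fixed] <- vfix; v[free] <- NA_real_
    return(finish(v, "numerical-failure", note = conditionMessage(fit)))
  }

  vf <- fit$solution
  # dropped (linearly dependent) equality rows must still hold, else the
  # original system was inconsistent
  if (length(keep) < nrow(Aeq_f)) {
    dropped <- setdiff(seq_len(nrow(Aeq_f)), keep)
    res_drop <- max(abs(Aeq_f[dropped, , drop = FALSE] %*% vf - beq_f[dropped]))
    if (res_drop > 1e-6 * rel_scale(vf)) {
      v <- numeric(n); v[fixed] <- vfix; v[free] <- vf
      return(finish(v, "infeasible",
                    note = "linearly dependent balance rows are inconsistent"))
    }
  }

  vf <- polish_active_set(vf, w[free], Ak, bk, lbf, ubf)

  v <- numeric(n)
  v[fixed] <- vfix
  v[free] <- vf

  cap_hit <- (!is.finite(lb[free]) & vf < -0.99 * big_m) |
             (!is.finite(ub[free]) & vf > 0.99 * big_m)
  note <- NULL
  if (any(cap_hit)) {
    note <- sprintf("flux within 1%% of the %g unbounded-marker cap: %s",
                    big_m, paste(ids[free][cap_hit], collapse = ", "))
    vf_warn("%s", note)
  }
  finish(v, "optimal", note = note)
}

# exact re-solve on the identified active set: fluxes at (finite) bounds are
# frozen, the rest solved from the equality-constrained KKT system
polish_active_set <- function(vf, w, Ak, bk, lbf, ubf) {
  scale <- rel_scale(vf)
  act <- (vf - lbf <= 1e-7 * scale) | (ubf - vf <= 1e-7 * scale)
  z <- ifelse(vf - lbf <= 1e-7 * scale, lbf, ubf)
  idx <- which(!act)
  if (length(idx) == 0L) return(vf)
  A1 <- Ak[, idx, drop = FALSE]
  b1 <- bk - (if (any(act)) Ak[, act, drop = FALSE] %*% z[act] else 0)
  m1 <- nrow(A1)
  K <- rbind(cbind(diag(2 * w[idx], length(idx)), t(A1)),
             cbind(A1, matrix(0, m1, m1)))
  rhs <- c(rep(0, length(idx)), b1)
  sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
  if (is.null(sol)) sol <- pinv(K) %*% rhs
  cand <- vf
  cand[act] <- z[act]
  cand[idx] <- sol[seq_along(idx)]
  ok <- all(cand >= lbf - 1e-10 * scale) && all(cand <= ubf + 1e-10 * scale) &&
    (m1 == 0L || max(abs(Ak %*% cand - bk)) <= 1e-8 * scale) &&
    sum(w * cand^2) <= sum(w * vf^2) + 1e-8 * (1 + sum(w * vf^2))
  if (ok) cand else vf
}

new_solution <- function(problem, v, status, tol, opt_tol, note = NULL) {
  names(v) <- problem$reaction_ids
  if (anyNA(v)) {
    bal <- NA_real_; bviol <- NA_real_; kkt <- NA_real_; obj <- NA_real_
    atb <- rep(NA, length(v))
  } else {
    obj <- sum(problem$weights * v^2)
    bal <- if (nrow(problem$S)) max(abs(problem$S %*% v)) else 0
    if (!is.null(problem$couplings)) {
      cv <- as.numeric(problem$couplings$A %*% v)
      bal <- max(bal, cv - problem$couplings$upper, problem$couplings$lower - cv, 0)
    }
    bviol <- max(problem$lb - v, v - problem$ub, 0)
    scale <- rel_scale(v)
    atb <- (is.finite(problem$lb) & v - problem$lb <= 1e-7 * scale) |
           (is.finite(problem$ub) & problem$ub - v <= 1e-7 * scale)
    kkt <- if (status == "optimal")
      stationarity_residual(problem, v)$residual else NA_real_
    if (status == "optimal" &&
        (bal > tol * scale || bviol > tol * scale)) {
      status <- "numerical-failure"
    }
  }
  structure(list(v = v, objective = obj, status = status,
                 balance_residual = bal, bound_violation = bviol,
                 kkt_residual = kkt, at_bound = atb, note = note,
                 tol = tol, opt_tol = opt_tol),
            class = "vf_solution")
}

#' @export
print.vf_solution <- function(x, ...) {
  cat(sprintf("Flux solution: status=%s, objective=%.6g\n", x$status, x$objective))
  cat(sprintf("  residuals: balance %.3g, bounds %.3g, KKT %.3g\n",
              x$balance_residual, x$bound_violation, x$kkt_residual))
  cat(sprintf("  fluxes at a bound: %d of %d\n", sum(x$at_bound), length(x$v)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Flux solution as a data frame
#'
#' @param x a `vf_solution`.
#' @param problem the `vf_problem` it solved (for bounds).
#' @return data.frame with `reaction_id`, `flux`, `lb`, `ub`, `at_bound`.
#' @export
solution_table <- function(x, problem) {
  data.frame(reaction_id = problem$reaction_ids, flux = as.numeric(x$v),
             lb = problem$lb, ub = problem$ub,
             at_bound = as.integer(x$at_bound), stringsAsFactors = FALSE)
}
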
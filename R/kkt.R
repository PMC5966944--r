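# least-squares reconstruction of KKT multipliers at a candidate optimum.
# Stationarity: 2 W v = Aeq' lambda + mu_lb - mu_ub + Ac' nu, with
# multipliers only on active constraints and sign constraints on the
# inequality multipliers.
stationarity_residual <- function(problem, v, act_tol = 1e-6) {
  n <- length(v)
  scale <- rel_scale(v)
  g <- 2 * problem$weights * v

  cols <- list()
  kindv <- character(0)
  if (nrow(problem$S)) {
    cols <- c(cols, list(t(problem$S)))
    kindv <- c(kindv, rep("eq", nrow(problem$S)))
  }
  if (!is.null(problem$couplings)) {
    cp <- problem$couplings
    for (i in seq_len(nrow(cp$A))) {
      a <- cp$A[i, ]
      val <- sum(a * v)
      if (cp$lower[i] == cp$upper[i]) {
        cols <- c(cols, list(matrix(a, ncol = 1))); kindv <- c(kindv, "eq")
      } else {
        if (is.finite(cp$lower[i]) && val - cp$lower[i] <= act_tol * scale) {
          cols <- c(cols, list(matrix(a, ncol = 1))); kindv <- c(kindv, "ineq")
        }
        if (is.finite(cp$upper[i]) && cp$upper[i] - val <= act_tol * scale) {
          cols <- c(cols, list(matrix(-a, ncol = 1))); kindv <- c(kindv, "ineq")
        }
      }
    }
  }
  act_lb <- which(is.finite(problem$lb) & v - problem$lb <= act_tol * scale &
                    problem$lb != problem$ub)
  act_ub <- which(is.finite(problem$ub) & problem$ub - v <= act_tol * scale &
                    problem$lb != problem$ub)
  fixed <- which(problem$lb == problem$ub)
  for (i in act_lb) { e <- numeric(n); e[i] <- 1
    cols <- c(cols, list(matrix(e, ncol = 1))); kindv <- c(kindv, "ineq") }
  for (i in act_ub) { e <- numeric(n); e[i] <- -1
    cols <- c(cols, list(matrix(e, ncol = 1))); kindv <- c(kindv, "ineq") }
  for (i in fixed) { e <- numeric(n); e[i] <- 1
    cols <- c(cols, list(matrix(e, ncol = 1))); kindv <- c(kindv, "eq") }

  M <- do.call(cbind, cols)
  if (is.null(M) || ncol(M) == 0L) {
    return(list(residual = max(abs(g)) / (1 + max(abs(g))),
                sign_violation = 0, multipliers = numeric(0), kinds = character(0)))
  }
  theta <- as.numeric(pinv(M) %*% g)
  resid <- max(abs(g - M %*% theta)) / (1 + max(abs(g)))
  sign_viol <- if (any(kindv == "ineq"))
    max(0, -min(theta[kindv == "ineq"])) else 0
  list(residual = resid, sign_violation = sign_viol,
       multipliers = theta, kinds = kindv)
}

#' Verify Karush-Kuhn-Tucker optimality of a flux solution
#'
#' Reconstructs Lagrange multipliers by least squares on the active
#' constraint set and reports the residual of each optimality block:
#' stationarity, primal feasibility (mass balance and bounds),
#' complementary slackness, and the sign of the multipliers on active
#' inequality constraints. A genuine optimum of the strictly convex program
#' passes every block; a perturbed flux vector fails stationarity.
#'
#' @param problem the `vf_problem`.
#' @param solution a `vf_solution` with `status == "optimal"`.
#' @param tol acceptance tolerance per block (default `1e-6`).
#' @return list of class `vf_kkt` with per-block residuals and `ok`.
#' @export
check_kkt <- function(problem, solution, tol = 1e-6) {
  if (!identical(solution$status, "optimal"))
    vf_stop("check_kkt expects an optimal solution (got status '%s')", solution$status)
  v <- as.numeric(solution$v)
  scale <- rel_scale(v)
  st <- stationarity_residual(problem, v)

  bal <- if (nrow(problem$S)) max(abs(problem$S %*% v)) / scale else 0
  if (!is.null(problem$couplings)) {
    cv <- as.numeric(problem$couplings$A %*% v)
    bal <- max(bal, (cv - problem$couplings$upper) / scale,
               (problem$couplings$lower - cv) / scale)
  }
  bounds <- max(problem$lb - v, v - problem$ub, 0) / scale

  # complementarity: multipliers were only assigned to active constraints,
  # so the product |mu * slack| is bounded by |mu| * activation tolerance
  act_slack <- pmin(abs(v - problem$lb), abs(problem$ub - v))
  comp <- 0
  if (length(st$multipliers)) {
    ineq_mu <- st$multipliers[st$kinds == "ineq"]
    if (length(ineq_mu)) comp <- max(abs(ineq_mu)) * 1e-6
  }

  out <- list(stationarity = st$residual,
              primal_balance = max(bal, 0),
              primal_bounds = bounds,
              complementarity = comp,
              multiplier_sign_violation = st$sign_violation,
              multipliers = st$multipliers,
              multiplier_kinds = st$kinds,
              tol = tol)
  out$ok <- with(out, stationarity <= tol && primal_balance <= tol &&
                   primal_bounds <= tol && multiplier_sign_violation <= tol)
  structure(out, class = "vf_kkt")
}

#' @export
print.vf_kkt <- function(x, ...) {
  cat(sprintf("KKT report (%s):\n", if (x$ok) "PASS" else "FAIL"))
  for (b in c("stationarity", "primal_balance", "primal_bounds",
              "complementarity", "multiplier_sign_violation"))
    cat(sprintf("  %-26s %.3g\n", b, x[[b]]))
  invisible(x)
}
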
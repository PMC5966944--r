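#' Construct a flux problem
#'
#' The quadratic flux-minimization program
#' \deqn{\min_v \sum_i w_i v_i^2 \quad \mathrm{s.t.}\quad S v = 0,\;
#'       c_l \le A v \le c_u,\; lb \le v \le ub}
#' with `S` the internal-metabolite stoichiometric matrix and `A` optional
#' coupling rows (e.g. the respiration constraint on `Vnrj1 + Vnrj2`).
#' Unbounded entries are `-Inf`/`Inf` markers; they are converted to a large
#' finite cap only at solver hand-off.
#'
#' @param S numeric matrix, internal metabolites x reactions.
#' @param lb,ub numeric bounds per reaction (`-Inf`/`Inf` allowed).
#' @param reaction_ids character, column labels of `S` by default.
#' @param couplings optional list with `A` (k x n matrix), `lower`, `upper`
#'   (length-k right-hand sides; equal values give an equality row) and
#'   optional `labels`.
#' @param weights strictly positive objective weights (default 1).
#' @return a `vf_problem`.
#' @export
flux_problem <- function(S, lb, ub, reaction_ids = colnames(S),
                         couplings = NULL, weights = NULL) {
  S <- as.matrix(S)
  n <- ncol(S)
  if (is.null(reaction_ids)) reaction_ids <- paste0("r", seq_len(n))
  weights <- weights %||% rep(1, n)
  if (length(lb) != n || length(ub) != n || length(weights) != n)
    vf_stop("lb, ub, weights must have length ncol(S) = %d", n)
  if (any(!is.finite(weights)) || any(weights <= 0))
    vf_stop("objective weights must be finite and > 0")
  if (any(is.na(lb)) || any(is.na(ub)))
    vf_stop("bounds must not be NA")
  bad <- which(lb > ub)
  if (length(bad))
    vf_stop("contradictory bounds (lb > ub) for reaction(s): %s",
            paste(reaction_ids[bad], collapse = ", "))
  if (!is.null(couplings)) {
    couplings$A <- as.matrix(couplings$A)
    k <- nrow(couplings$A)
    if (ncol(couplings$A) != n)
      vf_stop("coupling matrix must have %d columns", n)
    if (length(couplings$lower) != k || length(couplings$upper) != k)
      vf_stop("coupling right-hand sides must have length %d", k)
    if (any(couplings$lower > couplings$upper))
      vf_stop("contradictory coupling bounds (lower > upper)")
    couplings$labels <- couplings$labels %||% paste0("coupling", seq_len(k))
  }
  structure(list(S = S, lb = as.numeric(lb), ub = as.numeric(ub),
                 weights = as.numeric(weights),
                 reaction_ids = as.character(reaction_ids),
                 couplings = couplings),
            class = "vf_problem")
}

#' @export
print.vf_problem <- function(x, ...) {
  nfix <- sum(x$lb == x$ub)
  cat(sprintf("Flux problem: %d reactions, %d balanced metabolites, %d coupling row(s)\n",
              ncol(x$S), nrow(x$S),
              if (is.null(x$couplings)) 0L else nrow(x$couplings$A)))
  cat(sprintf("  fixed fluxes (lb = ub): %d; finite bounds: %d lower, %d upper\n",
              nfix, sum(is.finite(x$lb)), sum(is.finite(x$ub))))
  invisible(x)
}

#' Scale a flux problem
#'
#' Multiplies every finite bound and coupling right-hand side by `lambda`.
#' Because the feasible set and the quadratic objective are positively
#' homogeneous, the optimal flux vector scales by exactly `lambda`.
#'
#' @param problem a `vf_problem`.
#' @param lambda positive scalar.
#' @return the scaled `vf_problem`.
#' @export
scale_problem <- function(problem, lambda) {
  if (!is_scalar_number(lambda) || lambda <= 0) vf_stop("lambda must be > 0")
  problem$lb <- problem$lb * lambda
  problem$ub <- problem$ub * lambda
  if (!is.null(problem$couplings)) {
    problem$couplings$lower <- problem$couplings$lower * lambda
    problem$couplings$upper <- problem$couplings$upper * lambda
  }
  problem
}
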
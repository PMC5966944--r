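`%||%` <- function(a, b) if (is.null(a)) b else a

vf_stop <- function(fmt, ..., class = "vitisflux_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "vitisflux_error")))
}

vf_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

#' Moore-Penrose pseudo-inverse via SVD
#'
#' Small helper used by the enumeration oracle and the KKT auditor, kept
#' independent of the production QP backend.
#' @param A numeric matrix.
#' @param tol singular values below `tol * max(sv)` are treated as zero.
#' @return the pseudo-inverse of `A`.
#' @keywords internal
pinv <- function(A, tol = 1e-11) {
  if (length(A) == 0L) return(t(A))
  s <- svd(A)
  keep <- s$d > tol * max(s$d, .Machine$double.eps)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# stable scale for relative comparisons
rel_scale <- function(x) 1 + max(abs(x), 0)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
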
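#' Numerical control settings
#'
#' Central place for the numerical tolerances used across the package.
#'
#' @param pinv_rtol Relative singular-value cutoff for the pseudoinverse,
#'   multiplied by `max(dim(A)) * max(singular values)`. The default is machine
#'   epsilon, giving the customary cutoff `max(dim) * eps * sigma_max`.
#' @param projector_tol Tolerance (relative Frobenius norm) used when checking
#'   projector identities such as idempotence.
#' @param cv_tie_rtol Relative tolerance within which two cross-validation
#'   errors are considered tied (ties broken towards smaller gamma, then
#'   smaller order).
#'
#' @return A list of class `"obsp_control"`.
#' @export
#' @examples
#' obsp_control()
obsp_control <- function(pinv_rtol = .Machine$double.eps,
                         projector_tol = 1e-8,
                         cv_tie_rtol = 1e-12) {
  stopifnot(pinv_rtol > 0, projector_tol > 0, cv_tie_rtol >= 0)
  structure(
    list(
      pinv_rtol = pinv_rtol,
      projector_tol = projector_tol,
      cv_tie_rtol = cv_tie_rtol
    ),
    class = "obsp_control"
  )
}

abort_sideobsp <- function(message, class) {
  rlang::abort(message, class = c(paste0("sideobsp_", class), "sideobsp_error"))
}

warn_ill_posed <- function(message, rank_report = NULL) {
  rlang::warn(message,
    class = c("sideobsp_ill_posed", "sideobsp_warning"),
    rank_report = rank_report
  )
}

check_finite_matrix <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_sideobsp(
      sprintf("`%s` must be numeric with all entries finite.", name),
      "invalid_input"
    )
  }
  invisible(x)
}

#' Moore-Penrose pseudoinverse with an SVD cutoff
#'
#' Singular values below `max(dim(a)) * rtol * max(d)` are treated as zero.
#' Returned alongside (as attributes) are the numerical rank and the smallest
#' retained singular value, which downstream code uses for conditioning
#' diagnostics.
#'
#' @param a Numeric matrix.
#' @param rtol Relative cutoff; see [obsp_control()].
#' @return The pseudoinverse of `a`, with attributes `rank` and `min_sv`.
#' @export
#' @examples
#' pinv(diag(c(2, 0)))
pinv <- function(a, rtol = .Machine$double.eps) {
  a <- as.matrix(a)
  check_finite_matrix(a, "a")
  if (length(a) == 0L) {
    out <- matrix(0, ncol(a), nrow(a))
    attr(out, "rank") <- 0L
    attr(out, "min_sv") <- NA_real_
    return(out)
  }
  sv <- svd(a)
  cutoff <- max(dim(a)) * rtol * max(sv$d, 0)
  keep <- sv$d > cutoff
  r <- sum(keep)
  if (r == 0L) {
    out <- matrix(0, ncol(a), nrow(a))
  } else {
    out <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  }
  attr(out, "rank") <- as.integer(r)
  attr(out, "min_sv") <- if (r > 0L) min(sv$d[keep]) else NA_real_
  out
}

mat_rank <- function(a, rtol = .Machine$double.eps) {
  a <- as.matrix(a)
  if (length(a) == 0L) return(0L)
  d <- svd(a, nu = 0, nv = 0)$d
  as.integer(sum(d > max(dim(a)) * rtol * max(d, 0)))
}
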
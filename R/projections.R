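#' Partition of a design matrix into a target block and the rest
#'
#' Oblique projection works on a two-way split of the regressor matrix
#' `A = [A_k A_rest]` (up to column order): the block `A_k` spanning the target
#' signal subspace and the concatenation `A_rest` of all remaining blocks,
#' which defines the reference subspace the projection follows.
#'
#' @param A_k Numeric matrix, the target block.
#' @param A_rest Numeric matrix (possibly 0 columns), the remaining blocks.
#' @param k Integer index of the target block in the original design.
#' @return An object of class `"block_partition"`.
#' @export
block_partition <- function(A_k, A_rest, k = 1L) {
  A_k <- as.matrix(A_k)
  A_rest <- as.matrix(A_rest)
  check_finite_matrix(A_k, "A_k")
  if (length(A_rest)) check_finite_matrix(A_rest, "A_rest")
  if (nrow(A_rest) == 0L && ncol(A_rest) == 0L) {
    A_rest <- matrix(0, nrow(A_k), 0L)
  }
  if (nrow(A_k) != nrow(A_rest)) {
    abort_sideobsp("`A_k` and `A_rest` must have the same number of rows.",
      "invalid_input")
  }
  structure(list(A_k = A_k, A_rest = A_rest, k = as.integer(k)),
    class = "block_partition")
}

#' Orthogonal projector onto the null space of a block's transpose
#'
#' Computes `Q = I - A_rest (A_rest' A_rest)^+ A_rest'`, the orthogonal
#' projector onto `Null(A_rest')`. Applying `Q` to a signal removes every
#' component that lies in the span of the reference regressors. Internally the
#' projector is formed from an SVD basis of the column space, which is
#' numerically equivalent and rank-aware.
#'
#' @param A_rest Numeric matrix (rows = observations). Zero columns give the
#'   identity.
#' @param control Numerical settings, see [obsp_control()].
#' @return A symmetric idempotent matrix of size `nrow(A_rest)`.
#' @export
#' @examples
#' complement_projector(cbind(c(1, 0)))
complement_projector <- function(A_rest, control = obsp_control()) {
  A_rest <- as.matrix(A_rest)
  if (nrow(A_rest) < 1L) {
    abort_sideobsp("`A_rest` must have at least one row.", "invalid_input")
  }
  n <- nrow(A_rest)
  if (ncol(A_rest) == 0L) return(diag(n))
  check_finite_matrix(A_rest, "A_rest")
  sv <- svd(A_rest, nv = 0)
  cutoff <- max(dim(A_rest)) * control$pinv_rtol * max(sv$d, 0)
  keep <- sv$d > cutoff
  if (!any(keep)) return(diag(n))
  U <- sv$u[, keep, drop = FALSE]
  diag(n) - tcrossprod(U)
}

#' Oblique projector onto a target block along the remaining blocks
#'
#' Builds the pair of projectors used by the decomposition: the complement
#' projector `Q` of the reference blocks and the oblique projector
#' `P = A_k (A_k' Q A_k)^+ A_k' Q`, which maps any signal onto `span(A_k)`
#' following the direction of `span(A_rest)`. When the two spans overlap (the
#' projection is ill-defined) a warning of class `"sideobsp_ill_posed"` is
#' emitted and the pseudoinverse solution is returned.
#'
#' Projectors are exposed for inspection and testing; the solver itself never
#' materializes them (see [solve_block()]).
#'
#' @param part A [block_partition()].
#' @param control Numerical settings.
#' @return A list of class `"projector_pair"` with elements `Q`, `P_oblique`,
#'   `rank_Q` and `cond_report` (smallest retained singular value and the rank
#'   of `A_k' Q A_k`).
#' @export
#' @examples
#' part <- block_partition(cbind(c(1, 1)), cbind(c(1, 0)))
#' oblique_projector(part)$P_oblique
oblique_projector <- function(part, control = obsp_control()) {
  stopifnot(inherits(part, "block_partition"))
  A_k <- part$A_k
  A_rest <- part$A_rest
  Q <- complement_projector(A_rest, control)
  check_rank_overlap(A_k, A_rest, control)
  QAk <- Q %*% A_k
  M <- crossprod(A_k, QAk)
  Mi <- pinv(M, control$pinv_rtol)
  P <- A_k %*% Mi %*% crossprod(A_k, Q)
  structure(
    list(
      Q = Q,
      P_oblique = P,
      rank_Q = nrow(Q) - mat_rank(A_rest, control$pinv_rtol),
      cond_report = list(
        min_sv = attr(Mi, "min_sv"),
        rank_M = attr(Mi, "rank"),
        p = ncol(A_k)
      )
    ),
    class = "projector_pair"
  )
}

check_rank_overlap <- function(A_k, A_rest, control = obsp_control()) {
  r_k <- mat_rank(A_k, control$pinv_rtol)
  if (r_k < ncol(A_k)) {
    warn_ill_posed(
      sprintf(paste0(
        "Target block is rank deficient (rank %d < %d columns); its delayed ",
        "copies are collinear and the projection is ill-defined."),
        r_k, ncol(A_k)),
      rank_report = list(rank_k = r_k, cols_k = ncol(A_k))
    )
    return(invisible(TRUE))
  }
  if (ncol(A_rest) == 0L) return(invisible(FALSE))
  r_rest <- mat_rank(A_rest, control$pinv_rtol)
  r_joint <- mat_rank(cbind(A_k, A_rest), control$pinv_rtol)
  overlap <- r_joint < r_k + r_rest
  if (overlap) {
    warn_ill_posed(
      sprintf(paste0(
        "Target and reference subspaces overlap (rank [A_k A_rest] = %d < ",
        "%d + %d); the oblique projection is ill-defined and the ",
        "pseudoinverse (regularized) solution is returned."
      ), r_joint, r_k, r_rest),
      rank_report = list(rank_k = r_k, rank_rest = r_rest, rank_joint = r_joint)
    )
  }
  invisible(overlap)
}

#' Generalized least squares estimate
#'
#' Solves `min (y - Ax)' Sigma_inv (y - Ax)` in closed form,
#' `(A' Sigma_inv A)^+ A' Sigma_inv y`. With `Sigma_inv` equal to the
#' complement projector of a reference block, the fitted values `A x` equal an
#' oblique projection of `y` -- the connection the decomposition exploits.
#'
#' @param A Design matrix.
#' @param y Response vector.
#' @param Sigma_inv Symmetric positive semidefinite weight matrix; defaults to
#'   the identity (ordinary least squares).
#' @param control Numerical settings.
#' @return Coefficient vector.
#' @export
gls_estimate <- function(A, y, Sigma_inv = NULL, control = obsp_control()) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  check_finite_matrix(A, "A")
  check_finite_matrix(y, "y")
  if (nrow(A) != length(y)) {
    abort_sideobsp("`A` and `y` have incompatible dimensions.", "invalid_input")
  }
  if (is.null(Sigma_inv)) {
    return(drop(pinv(A, control$pinv_rtol) %*% y))
  }
  Sigma_inv <- as.matrix(Sigma_inv)
  check_finite_matrix(Sigma_inv, "Sigma_inv")
  if (nrow(Sigma_inv) != nrow(A) || ncol(Sigma_inv) != nrow(A)) {
    abort_sideobsp("`Sigma_inv` must be square and conformable with `A`.",
      "invalid_input")
  }
  if (max(abs(Sigma_inv - t(Sigma_inv))) >
      control$projector_tol * max(1, max(abs(Sigma_inv)))) {
    abort_sideobsp("`Sigma_inv` must be symmetric.", "invalid_input")
  }
  SA <- Sigma_inv %*% A
  drop(pinv(crossprod(A, SA), control$pinv_rtol) %*% crossprod(SA, y))
}

#' Least-squares solution of the complement-projected regression
#'
#' Solves the regression `Q y = Q A_k x + Q e` (the reference blocks projected
#' out), whose solution `(A_k' Q A_k)^+ A_k' Q y` coincides with the
#' least-squares solution of the obliquely projected problem
#' `P y = P A x`. The projector `Q` is applied implicitly, as residuals of a
#' least-squares fit against `A_rest`, so no `n x n` matrix is formed.
#'
#' @param part A [block_partition()].
#' @param y Response vector (same length as the design rows).
#' @param control Numerical settings.
#' @return Coefficient vector of length `ncol(part$A_k)`.
#' @export
equivalent_ls_solution <- function(part, y, control = obsp_control()) {
  stopifnot(inherits(part, "block_partition"))
  y <- as.numeric(y)
  check_finite_matrix(y, "y")
  if (length(y) != nrow(part$A_k)) {
    abort_sideobsp("`y` must match the design rows.", "invalid_input")
  }
  check_rank_overlap(part$A_k, part$A_rest, control)
  QAk <- apply_complement(part$A_rest, part$A_k, control)
  drop(pinv(crossprod(QAk), control$pinv_rtol) %*% crossprod(QAk, y))
}

# Apply Q = I - P(A_rest) to the columns of m without forming Q:
# residuals of the LS fit of each column of m on A_rest.
apply_complement <- function(A_rest, m, control = obsp_control()) {
  m <- as.matrix(m)
  if (ncol(A_rest) == 0L) return(m)
  sv <- svd(A_rest, nv = 0)
  cutoff <- max(dim(A_rest)) * control$pinv_rtol * max(sv$d, 0)
  U <- sv$u[, sv$d > cutoff, drop = FALSE]
  if (ncol(U) == 0L) return(m)
  m - U %*% crossprod(U, m)
}
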
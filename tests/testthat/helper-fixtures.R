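# Independent projector oracle: SVD-based pseudoinverse and projectors,
# written with base R only so the tests do not reuse the package's pinv().
ginv_svd <- function(a, tol = 1e-10) {
  sv <- svd(a)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) return(matrix(0, ncol(a), nrow(a)))
  sv$v[, keep, drop = FALSE] %*% (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

orth_proj_oracle <- function(a) {
  sv <- svd(a, nv = 0)
  u <- sv$u[, sv$d > 1e-10 * max(sv$d), drop = FALSE]
  tcrossprod(u)
}

# Random two-block design; `shared` adds a common component to both blocks so
# their spans are correlated (but not overlapping).
make_blocks <- function(n, p_k, p_rest, seed, shared = 0) {
  withr::with_seed(seed, {
    A_k <- matrix(stats::rnorm(n * p_k), n)
    A_rest <- matrix(stats::rnorm(n * p_rest), n)
    if (shared > 0) {
      common <- stats::rnorm(n)
      A_k <- A_k + shared * common
      A_rest <- A_rest + shared * common
    }
    list(A_k = A_k, A_rest = A_rest)
  })
}

# Direct convolution oracle for the Hankel design: y[n] = sum_m h[m+1] s[n-m]
naive_conv_trim <- function(s, h, p) {
  n <- length(s)
  vapply((p + 1):n, function(t) sum(h * s[t - seq_along(h) + 1]), numeric(1))
}

relerr <- function(a, b) {
  na <- sqrt(sum((a - b)^2))
  na / max(sqrt(sum(b^2)), .Machine$double.eps)
}
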
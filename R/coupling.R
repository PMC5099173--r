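#' Pairwise coupling (information transfer) between two signals
#'
#' Quantifies how much the past of `x` helps predict `y`. The default
#' estimator is an information-transfer measure: the reduction in corrected
#' conditional entropy of `y` when the quantized past of `x` is added to the
#' quantized past of `y` itself (uniform quantization into `levels` bins,
#' embedding vectors of `embedding` past samples; the correction of the
#' conditional entropy compensates the downward bias of sparse pattern
#' counts by substituting the marginal entropy for patterns observed once).
#' A linear alternative (`method = "linear"`) reports the fraction of
#' variance of `y` explained by `x` at lags `0..embedding`, which satisfies
#' the same contract (non-negative, zero in expectation under independence,
#' increasing with linear coupling, invariant to affine rescaling) with a
#' deterministic closed form.
#'
#' Both signals are internally standardized, so the measure is invariant to
#' affine rescaling of either signal.
#'
#' @param x,y Numeric vectors of equal length (`>= 100`).
#' @param method `"infotransfer"` (default) or `"linear"`.
#' @param embedding Embedding length L (past samples per signal).
#' @param levels Number of quantization levels (infotransfer only).
#' @return A single non-negative number (bits for `"infotransfer"`, variance
#'   fraction for `"linear"`).
#' @export
#' @examples
#' x <- rnorm(500)
#' coupling_metric(x, c(0, x[-500]))       # strong coupling
coupling_metric <- function(x, y, method = c("infotransfer", "linear"),
                            embedding = 2L, levels = 6L) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort_sideobsp("`x` and `y` must have equal length.", "invalid_input")
  }
  if (length(x) < 100L) {
    abort_sideobsp("Coupling estimation needs at least 100 samples.",
      "invalid_input")
  }
  check_finite_matrix(x, "x")
  check_finite_matrix(y, "y")
  if (method == "linear") {
    return(linear_coupling(x, y, lags = embedding))
  }
  qx <- quantize_uniform(x, levels)
  qy <- quantize_uniform(y, levels)
  it_core(qx, qy, L = as.integer(embedding), Q = as.integer(levels))
}

quantize_uniform <- function(v, Q) {
  r <- range(v)
  if (r[1] == r[2]) return(integer(length(v)))
  pmin(Q - 1L, as.integer(floor((v - r[1]) / (r[2] - r[1]) * Q)))
}

# Information transfer on pre-quantized integer series (codes 0..Q-1).
it_core <- function(qx, qy, L, Q) {
  n <- length(qy)
  idx <- (L + 1L):n
  tgt <- qy[idx]
  ycond <- rep(0, length(idx))
  xcond <- rep(0, length(idx))
  for (j in seq_len(L)) {
    ycond <- ycond * Q + qy[idx - j]
    xcond <- xcond * Q + qx[idx - j]
  }
  h_tgt <- entropy_counts(tabulate(tgt + 1L, Q))
  cce1 <- corrected_cond_entropy(tgt, ycond, Q, h_tgt)
  cce2 <- corrected_cond_entropy(tgt, ycond * Q^L + xcond, Q, h_tgt)
  max(0, cce1 - cce2)
}

corrected_cond_entropy <- function(tgt, cond, Q, h_tgt) {
  uc <- unique(cond)
  cid <- match(cond, uc)
  n_cond <- tabulate(cid, length(uc))
  joint <- (cid - 1L) * Q + tgt
  uj <- unique(joint)
  n_joint <- tabulate(match(joint, uj), length(uj))
  ce <- entropy_counts(n_joint) - entropy_counts(n_cond)
  perc_single <- sum(n_cond == 1L) / length(tgt)
  ce + perc_single * h_tgt
}

entropy_counts <- function(cnt) {
  cnt <- cnt[cnt > 0]
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

linear_coupling <- function(x, y, lags = 2L) {
  lags <- as.integer(lags)
  n <- length(x)
  idx <- (lags + 1L):n
  X <- vapply(0:lags, function(j) x[idx - j], numeric(length(idx)))
  yy <- y[idx] - mean(y[idx])
  if (sum(yy^2) == 0) return(0)
  X <- sweep(X, 2L, colMeans(X))
  beta <- pinv(crossprod(X)) %*% crossprod(X, yy)
  fit <- X %*% beta
  max(0, sum(fit * yy) / sum(yy^2))
}

#' Surrogate-null significance of a coupling value
#'
#' Compares the observed coupling to a null distribution built from circular
#' time-shift surrogates of `x` (shifts drawn uniformly, at least `min_shift`
#' samples away from zero lag), which preserve the marginal distribution and
#' autocorrelation of both signals while destroying their alignment.
#'
#' @inheritParams coupling_metric
#' @param n_surrogates Number of surrogate shifts.
#' @param min_shift Minimum shift magnitude in samples.
#' @param probs Null quantile used as the significance threshold.
#' @param seed Integer seed for the surrogate shifts.
#' @return A list: `metric`, `threshold`, `significant`, `p_value`, `null`
#'   (the surrogate values).
#' @export
coupling_significance <- function(x, y, method = c("infotransfer", "linear"),
                                  embedding = 2L, levels = 6L,
                                  n_surrogates = 199L, min_shift = 50L,
                                  probs = 0.95, seed = 1L) {
  method <- match.arg(method)
  n <- length(x)
  if (n - 2L * min_shift < 1L) {
    abort_sideobsp("Record too short for the requested `min_shift`.",
      "invalid_input")
  }
  obs <- coupling_metric(x, y, method, embedding, levels)
  shifts <- withr::with_seed(as.integer(seed),
    sample(seq.int(min_shift, n - min_shift), n_surrogates, replace = TRUE))
  null <- vapply(shifts, function(s) {
    xs <- c(x[(s + 1L):n], x[1:s])
    coupling_metric(xs, y, method, embedding, levels)
  }, numeric(1))
  thr <- stats::quantile(null, probs, names = FALSE)
  list(
    metric = obs,
    threshold = thr,
    significant = obs > thr,
    p_value = (1 + sum(null >= obs)) / (1 + n_surrogates),
    null = null
  )
}

#' Coupling matrix between input channels and estimated components
#'
#' Entry `(j, i)` is the coupling between measured input channel `j` and the
#' estimated partial contribution of input `i`. A successful decomposition
#' shows the diagonal pattern: each component couples to its own input and to
#' no other (off-diagonals indistinguishable from the surrogate null).
#'
#' @param data Data frame or [signal_set()] holding the measured channels the
#'   fit used.
#' @param components A [side_obsp()] fit, or a matrix/data frame of component
#'   columns aligned with the tail rows of `data`.
#' @inheritParams coupling_significance
#' @param significance If `TRUE`, attach the surrogate-null significance of
#'   every entry.
#' @param probs Null quantile for the per-entry threshold. The default
#'   controls the family-wise error of the whole table at 5% by Bonferroni
#'   correction over its `d^2` entries, so a "clean" diagonal pattern is
#'   interpretable as a table-level statement.
#' @return An object of class `"coupling_matrix"`: `values`
#'   (inputs x components), and when requested `significant` and `p_values`
#'   of the same shape; plus the estimator settings.
#' @export
coupling_table <- function(data, components,
                           method = c("infotransfer", "linear"),
                           embedding = 2L, levels = 6L,
                           significance = FALSE, n_surrogates = 199L,
                           min_shift = 50L, probs = NULL, seed = 1L) {
  method <- match.arg(method)
  if (inherits(components, "side_obsp")) {
    comp_mat <- components$components
    input_names <- components$names$inputs
    target <- components$names$target
  } else {
    comp_mat <- as.matrix(components)
    input_names <- NULL
    target <- NULL
  }
  df <- if (inherits(data, "signal_set")) {
    m <- cbind(data$S)
    colnames(m) <- data$names$inputs
    as.data.frame(m)
  } else {
    as.data.frame(data)
  }
  if (is.null(input_names)) {
    input_names <- setdiff(
      names(df)[vapply(df, is.numeric, logical(1))], c("time", "t", target))
  }
  missing <- setdiff(input_names, names(df))
  if (length(missing)) {
    abort_sideobsp(sprintf("Input channel(s) not found: %s",
      paste(missing, collapse = ", ")), "invalid_input")
  }
  if (is.null(probs)) {
    probs <- 1 - 0.05 / (length(input_names) * ncol(comp_mat))
  }
  n_comp <- nrow(comp_mat)
  n_data <- nrow(df)
  if (n_data < n_comp) {
    abort_sideobsp("Fewer data rows than component rows.", "invalid_input")
  }
  inputs <- as.matrix(df[(n_data - n_comp + 1L):n_data, input_names,
    drop = FALSE])
  d_in <- ncol(inputs)
  d_cmp <- ncol(comp_mat)
  comp_names <- colnames(comp_mat)
  if (is.null(comp_names)) comp_names <- paste0("component", seq_len(d_cmp))
  vals <- matrix(0, d_in, d_cmp, dimnames = list(input_names, comp_names))
  sig <- pval <- NULL
  if (significance) {
    sig <- matrix(NA, d_in, d_cmp, dimnames = dimnames(vals))
    pval <- matrix(NA_real_, d_in, d_cmp, dimnames = dimnames(vals))
  }
  for (j in seq_len(d_in)) {
    for (i in seq_len(d_cmp)) {
      if (significance) {
        res <- coupling_significance(inputs[, j], comp_mat[, i], method,
          embedding, levels, n_surrogates, min_shift, probs = probs,
          seed = seed + 1000L * j + i)
        vals[j, i] <- res$metric
        sig[j, i] <- res$significant
        pval[j, i] <- res$p_value
      } else {
        vals[j, i] <- coupling_metric(inputs[, j], comp_mat[, i], method,
          embedding, levels)
      }
    }
  }
  structure(
    list(values = vals, significant = sig, p_values = pval,
      method = method,
      params = list(embedding = embedding, levels = levels,
        n_surrogates = if (significance) n_surrogates else NULL,
        min_shift = if (significance) min_shift else NULL,
        probs = if (significance) probs else NULL),
      seed = seed),
    class = "coupling_matrix"
  )
}

#' @export
print.coupling_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("<coupling_matrix> %s estimator (inputs x components)\n",
    x$method))
  print(round(x$values, digits))
  if (!is.null(x$significant)) {
    cat("significant vs surrogate null:\n")
    print(x$significant)
  }
  invisible(x)
}
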
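#' Bundle synchronously sampled channels into a signal set
#'
#' @param data Data frame with one numeric column per channel (and optionally a
#'   time column, ignored here beyond alignment).
#' @param target Name of the output channel.
#' @param inputs Character vector of input channel names; defaults to every
#'   numeric column except `target` and `time`.
#' @param fs Sampling rate in Hz.
#' @param time Optional name of a time column carried through for alignment.
#' @return An object of class `"signal_set"` with fields `S` (N x d input
#'   matrix), `y`, `fs`, `names`, `time`.
#' @export
#' @examples
#' df <- data.frame(t = 0:9, a = rnorm(10), b = rnorm(10), y = rnorm(10))
#' signal_set(df, target = "y", fs = 1, time = "t")
signal_set <- function(data, target, inputs = NULL, fs = 1, time = NULL) {
  data <- as.data.frame(data)
  if (is.null(time)) {
    cand <- intersect(c("time", "t"), names(data))
    time <- if (length(cand)) cand[[1]] else NULL
  }
  if (!target %in% names(data)) {
    abort_sideobsp(sprintf("Target channel '%s' not found in the data.", target),
      "invalid_input")
  }
  if (is.null(inputs)) {
    inputs <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
      c(target, time))
  }
  missing <- setdiff(inputs, names(data))
  if (length(missing)) {
    abort_sideobsp(sprintf("Input channel(s) not found: %s",
      paste(missing, collapse = ", ")), "invalid_input")
  }
  if (length(inputs) == 0L) {
    abort_sideobsp("At least one input channel is required.", "invalid_input")
  }
  S <- as.matrix(data[inputs])
  y <- as.numeric(data[[target]])
  for (nm in c(inputs, target)) {
    col <- data[[nm]]
    bad <- which(!is.finite(col))
    if (length(bad)) {
      abort_sideobsp(sprintf(
        "Non-finite value in channel '%s' at row %d.", nm, bad[[1]]),
        "invalid_input")
    }
  }
  if (length(y) < 2L) {
    abort_sideobsp("Channels must contain at least 2 samples.", "invalid_input")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort_sideobsp("`fs` must be a positive sampling rate in Hz.",
      "invalid_input")
  }
  tvec <- if (!is.null(time)) as.numeric(data[[time]]) else
    seq(0, by = 1 / fs, length.out = length(y))
  structure(
    list(S = S, y = y, fs = fs,
      names = list(inputs = inputs, target = target),
      time = tvec),
    class = "signal_set"
  )
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> %d samples @ %.4g Hz; inputs: %s; target: %s\n",
    length(x$y), x$fs, paste(x$names$inputs, collapse = ", "),
    x$names$target))
  invisible(x)
}

#' Block-Hankel expansion of one channel
#'
#' Column `j` (1-based) holds the channel delayed by `j - 1` samples; row `r`
#' corresponds to output time index `p + r` (1-based), so the matrix has
#' `N - p` rows and multiplying by an impulse-response vector of `p` taps
#' performs the causal moving-average convolution, aligned with the trimmed
#' output `s[(p+1):N]`.
#'
#' @param s Numeric vector of length `N`.
#' @param p Number of taps (model order), `1 <= p < N`.
#' @return `(N - p) x p` matrix with the Hankel property
#'   `A[i, j] == A[i - 1, j + 1]`.
#' @export
#' @examples
#' block_hankel(1:5, 2)
block_hankel <- function(s, p) {
  s <- as.numeric(s)
  check_finite_matrix(s, "s")
  n <- length(s)
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p)) {
    abort_sideobsp("`p` must be a positive integer.", "invalid_order")
  }
  if (p >= n) {
    abort_sideobsp(sprintf(
      "Order p = %d must be smaller than the signal length N = %d.", p, n),
      "invalid_order")
  }
  p <- as.integer(p)
  out <- matrix(0, n - p, p)
  for (j in seq_len(p)) {
    out[, j] <- s[(p - j + 2L):(n - j + 1L)]
  }
  out
}

#' Build the block-Hankel regressor design for a signal set
#'
#' Concatenates the per-channel Hankel blocks `A = [A_1, ..., A_d]` and trims
#' the output to the last `N - p` samples so rows and output are aligned.
#' Channels are mean-centered by default (the model describes deviations;
#' uncentered channels would load a collinear constant subspace into every
#' block). With `scale = TRUE` inputs are additionally scaled to unit
#' variance; estimated impulse responses are rescaled back on output by the
#' solver.
#'
#' @param sigset A [signal_set()].
#' @param p Model order (taps per input).
#' @param center,scale Preprocessing toggles (defaults `TRUE`, `FALSE`).
#' @return An object of class `"regressor_design"`: `A`, `p`, `d`,
#'   `block_cols` (list of column indices per input), `y_trim`, `time_trim`,
#'   `scales`, `names`.
#' @export
build_design <- function(sigset, p, center = TRUE, scale = FALSE) {
  stopifnot(inherits(sigset, "signal_set"))
  n <- length(sigset$y)
  d <- ncol(sigset$S)
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p)) {
    abort_sideobsp("`p` must be a positive integer.", "invalid_order")
  }
  if (n - p <= d * p) {
    abort_sideobsp(sprintf(paste0(
      "Design is underdetermined: N - p = %d rows for d*p = %d columns; ",
      "need N > %d (have N = %d)."), n - p, d * p, p * (d + 1), n),
      "design_underdetermined")
  }
  S <- sigset$S
  y <- sigset$y
  mu_s <- if (center) colMeans(S) else rep(0, d)
  mu_y <- if (center) mean(y) else 0
  S <- sweep(S, 2L, mu_s)
  y <- y - mu_y
  sd_s <- rep(1, d)
  if (scale) {
    sd_s <- apply(S, 2L, stats::sd)
    sd_s[sd_s == 0] <- 1
    S <- sweep(S, 2L, sd_s, "/")
  }
  blocks <- lapply(seq_len(d), function(k) block_hankel(S[, k], p))
  A <- do.call(cbind, blocks)
  block_cols <- lapply(seq_len(d), function(k) ((k - 1L) * p + 1L):(k * p))
  names(block_cols) <- sigset$names$inputs
  structure(
    list(
      A = A, p = as.integer(p), d = d, block_cols = block_cols,
      y_trim = y[(p + 1L):n],
      time_trim = sigset$time[(p + 1L):n],
      center = list(inputs = mu_s, target = mu_y),
      scales = sd_s,
      names = sigset$names
    ),
    class = "regressor_design"
  )
}

#' Extract the target/reference partition for one input block
#'
#' @param design A [build_design()] result.
#' @param k Input index (1-based).
#' @return A [block_partition()] with `A_k` the `k`-th Hankel block and
#'   `A_rest` the remaining blocks in original order.
#' @export
design_partition <- function(design, k) {
  stopifnot(inherits(design, "regressor_design"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > design$d ||
      k != round(k)) {
    abort_sideobsp(sprintf(
      "Block index k = %s is out of range 1..%d.", format(k), design$d),
      "invalid_index")
  }
  k <- as.integer(k)
  cols_k <- design$block_cols[[k]]
  block_partition(
    design$A[, cols_k, drop = FALSE],
    design$A[, -cols_k, drop = FALSE],
    k = k
  )
}
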
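#' First-difference regularization operator
#'
#' The `(p-1) x p` matrix `G` with `G[i, i] = -1`, `G[i, i+1] = 1`. Penalizing
#' `||G h||^2` shrinks differences between consecutive impulse-response taps,
#' enforcing the smooth responses expected of physiological subsystems;
#' constant vectors lie in its null space and are not penalized.
#'
#' @param p Model order, `p >= 2`.
#' @return A `(p - 1) x p` matrix.
#' @export
#' @examples
#' regularization_matrix(3)
regularization_matrix <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 2 || p != round(p)) {
    abort_sideobsp("`p` must be an integer >= 2.", "invalid_order")
  }
  p <- as.integer(p)
  G <- matrix(0, p - 1L, p)
  G[cbind(seq_len(p - 1L), seq_len(p - 1L))] <- -1
  G[cbind(seq_len(p - 1L), seq_len(p - 1L) + 1L)] <- 1
  G
}

#' Regularized impulse-response estimate for one input block
#'
#' Solves the complement-projected, Tikhonov-regularized problem for the
#' target block: `h = (A_k' Q A_k + gamma G'G)^+ A_k' Q y`. The projector `Q`
#' of the reference blocks is applied implicitly (residuals of a least-squares
#' fit against `A_rest`), so no dense `n x n` projector is ever formed.
#' With `gamma = 0` this is exactly the oblique-projection (equivalent
#' least-squares) solution.
#'
#' @param part A [block_partition()].
#' @param y_trim Trimmed output vector aligned with the design rows.
#' @param gamma Regularization constant, `>= 0`.
#' @param Gamma Regularization operator; defaults to
#'   [regularization_matrix()] of the block order.
#' @param control Numerical settings.
#' @return Impulse-response vector of length `ncol(part$A_k)`.
#' @export
solve_block <- function(part, y_trim, gamma = 0, Gamma = NULL,
                        control = obsp_control()) {
  stopifnot(inherits(part, "block_partition"))
  y_trim <- as.numeric(y_trim)
  check_finite_matrix(y_trim, "y_trim")
  if (length(y_trim) != nrow(part$A_k)) {
    abort_sideobsp("`y_trim` must match the design rows.", "invalid_input")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    abort_sideobsp("`gamma` must be a single non-negative number.",
      "invalid_parameter")
  }
  p <- ncol(part$A_k)
  if (is.null(Gamma)) {
    Gamma <- if (p >= 2L) regularization_matrix(p) else matrix(0, 0L, p)
  }
  QAk <- apply_complement(part$A_rest, part$A_k, control)
  M <- crossprod(QAk)
  if (gamma == 0) {
    # unregularized path: report overlap between target and reference spans
    check_rank_overlap(part$A_k, part$A_rest, control)
  } else {
    M <- M + gamma * crossprod(Gamma)
  }
  rhs <- crossprod(QAk, y_trim)
  drop(pinv(M, control$pinv_rtol) %*% rhs)
}

#' Decompose an output channel into per-input partial contributions
#'
#' Fits the moving-average (finite-impulse-response) model
#' `y[n] = sum_i sum_m s_i[n - m] h_i[m] + e[n]` on a block-Hankel design and
#' estimates each input's impulse response with an oblique-subspace-projection
#' solve: for input `k` the reference blocks (all other inputs) are projected
#' out with their complement projector before the regularized least-squares
#' fit, so dynamics shared between correlated inputs are assigned to the
#' correct subsystem rather than leaking across components. The partial
#' contribution of input `k` is then `yhat_k = A_k h_k`.
#'
#' @param data Data frame of synchronously sampled channels, or a
#'   [signal_set()].
#' @param target Output channel name.
#' @param inputs Input channel names; default: all other numeric columns.
#' @param fs Sampling rate (Hz).
#' @param order Model order `p` (taps per input), or `"auto"` to select by
#'   cross-validation over `order_grid`.
#' @param gamma Regularization constant, or `"auto"` to select by
#'   cross-validation over `gamma_grid`.
#' @param order_grid,gamma_grid,folds Cross-validation settings, see
#'   [cross_validate()]. Used only when `order` or `gamma` is `"auto"`.
#' @param center,scale Channel preprocessing (see [build_design()]).
#' @param projection `"oblique"` (the default) or `"none"` for naive
#'   per-input ordinary least squares (no decoupling; provided as the
#'   baseline that fails under correlated inputs).
#' @param control Numerical settings.
#' @return An object of class `"side_obsp"`: impulse responses `h`
#'   (`p x d`), `components` (`(N-p) x d`), `residual`, `fitted`, `y_trim`,
#'   `time_trim`, selected `p` and `gamma`, `cv_trace` (when CV ran), channel
#'   `names`, `fs`. Methods: [tidy.side_obsp()], [glance.side_obsp()],
#'   [autoplot.side_obsp()], `print`.
#' @export
#' @examples
#' bench <- generate_benchmark(seed = 1, n = 512, snr_db = Inf,
#'   rho = 0, output_mix_rho = 0)
#' fit <- side_obsp(bench$data, target = "y", order = 50)
#' glance(fit)
side_obsp <- function(data, target = "y", inputs = NULL, fs = 1,
                      order = 50, gamma = 0,
                      order_grid = NULL, gamma_grid = NULL, folds = 10,
                      center = TRUE, scale = FALSE,
                      projection = c("oblique", "none"),
                      control = obsp_control()) {
  projection <- match.arg(projection)
  sigset <- if (inherits(data, "signal_set")) data else
    signal_set(data, target = target, inputs = inputs, fs = fs)
  cv_trace <- NULL
  auto_order <- identical(order, "auto")
  auto_gamma <- identical(gamma, "auto")
  if (auto_order || auto_gamma) {
    if (auto_order && is.null(order_grid)) {
      abort_sideobsp("`order = \"auto\"` requires `order_grid`.",
        "invalid_parameter")
    }
    cv <- cross_validate(sigset,
      order_grid = if (auto_order) order_grid else order,
      gamma_grid = if (auto_gamma) gamma_grid else gamma,
      folds = folds, center = center, scale = scale, control = control)
    order <- cv$order
    gamma <- cv$gamma
    cv_trace <- cv$cv_trace
  }
  fit_side_obsp(sigset, p = order, gamma = gamma, center = center,
    scale = scale, projection = projection, control = control,
    cv_trace = cv_trace)
}

fit_side_obsp <- function(sigset, p, gamma, center = TRUE, scale = FALSE,
                          projection = "oblique",
                          control = obsp_control(), cv_trace = NULL) {
  design <- build_design(sigset, p, center = center, scale = scale)
  d <- design$d
  p <- design$p
  Gamma <- if (p >= 2L) regularization_matrix(p) else matrix(0, 0L, p)
  h <- matrix(0, p, d, dimnames = list(NULL, design$names$inputs))
  components <- matrix(0, nrow(design$A), d,
    dimnames = list(NULL, design$names$inputs))
  for (k in seq_len(d)) {
    part <- design_partition(design, k)
    if (projection == "none") {
      part <- block_partition(part$A_k, matrix(0, nrow(part$A_k), 0L), k)
    }
    nm <- design$names$inputs[[k]]
    h_k <- withCallingHandlers(
      solve_block(part, design$y_trim, gamma = gamma, Gamma = Gamma,
        control = control),
      sideobsp_ill_posed = function(w) {
        warn_ill_posed(sprintf("Input '%s': %s", nm, conditionMessage(w)),
          rank_report = attr(w, "rank_report"))
        invokeRestart("muffleWarning")
      },
      error = function(e) {
        if (inherits(e, "sideobsp_error")) {
          abort_sideobsp(sprintf("Input '%s': %s", nm, conditionMessage(e)),
            "block_solve")
        }
      }
    )
    components[, k] <- part$A_k %*% h_k
    h[, k] <- h_k / design$scales[[k]]
  }
  fitted <- rowSums(components)
  structure(
    list(
      h = h,
      components = components,
      fitted = fitted,
      residual = design$y_trim - fitted,
      y_trim = design$y_trim,
      time_trim = design$time_trim,
      p = p,
      gamma = gamma,
      cv_trace = cv_trace,
      names = design$names,
      fs = sigset$fs,
      projection = projection,
      center = design$center,
      control = control
    ),
    class = "side_obsp"
  )
}

#' Cross-validate the model order and regularization constant
#'
#' The reference-block projection is treated as a fixed preprocessing of the
#' record: for each candidate order the projected regressors `Q A_k` and
#' projected output `Q y` are formed once from the full record, and the
#' regularized fit is cross-validated over contiguous, non-overlapping time
#' blocks of the projected regression (shuffled folds would break serial
#' dependence). The fold error is the validation prediction error
#' `e = (1/N_v) ||(Qy)_v - (QA_k)_v h||^2`, summed over input blocks and
#' averaged over folds. The smoothness penalty already acts inside each fit;
#' adding it to the selection criterion as well would double-count it and
#' bias the choice (towards the largest order if weighted `1/p`, towards
#' `gamma = 0` if weighted by `gamma`), so model choice uses prediction
#' error alone. The reported optimum minimizes it, with ties (relative
#' tolerance `cv_tie_rtol`, on a scale set by the output variance so that
#' machine-zero errors compare as equal) broken towards smaller `gamma`,
#' then smaller order.
#'
#' @param data Data frame or [signal_set()].
#' @param target,inputs,fs Channel mapping (ignored when `data` is already a
#'   signal set).
#' @param order_grid Candidate orders (positive integers).
#' @param gamma_grid Candidate regularization constants; `NULL` gives 0 plus
#'   13 log-spaced values over `1e-6 ... 1e3` scaled by the mean of
#'   `trace(A_k' Q A_k) / p` across blocks (so the grid tracks the size of
#'   the normal-equation matrix and the unregularized fit is always a
#'   candidate).
#' @param folds Number of contiguous folds (`>= 2`).
#' @param center,scale,control See [side_obsp()].
#' @return A list of class `"obsp_cv"`: selected `order`, `gamma`, and the
#'   full `cv_trace` tibble (`order`, `gamma`, `cv_error`).
#' @export
cross_validate <- function(data, target = "y", inputs = NULL, fs = 1,
                           order_grid, gamma_grid = NULL, folds = 10,
                           center = TRUE, scale = FALSE,
                           control = obsp_control()) {
  sigset <- if (inherits(data, "signal_set")) data else
    signal_set(data, target = target, inputs = inputs, fs = fs)
  order_grid <- sort(unique(as.integer(order_grid)))
  if (length(order_grid) == 0L) {
    abort_sideobsp("`order_grid` must be non-empty.", "invalid_parameter")
  }
  if (!is.null(gamma_grid)) {
    gamma_grid <- sort(unique(as.numeric(gamma_grid)))
    if (length(gamma_grid) == 0L || any(gamma_grid < 0)) {
      abort_sideobsp("`gamma_grid` must be non-empty and non-negative.",
        "invalid_parameter")
    }
  }
  if (!is.numeric(folds) || length(folds) != 1L || folds < 2) {
    abort_sideobsp("`folds` must be at least 2.", "invalid_fold")
  }
  folds <- as.integer(folds)
  trace <- list()
  for (p in order_grid) {
    design <- build_design(sigset, p, center = center, scale = scale)
    n_rows <- nrow(design$A)
    if (n_rows < folds) {
      abort_sideobsp(sprintf(
        "Cannot split %d design rows into %d non-empty folds.", n_rows, folds),
        "invalid_fold")
    }
    fold_id <- contiguous_folds(n_rows, folds)
    Gamma <- if (p >= 2L) regularization_matrix(p) else matrix(0, 0L, p)
    GtG <- crossprod(Gamma)
    # project once per block from the full record
    proj <- lapply(seq_len(design$d), function(k) {
      part <- design_partition(design, k)
      QAk <- apply_complement(part$A_rest, part$A_k, control)
      Qy <- drop(apply_complement(part$A_rest, cbind(design$y_trim), control))
      list(QAk = QAk, Qy = Qy)
    })
    gammas <- gamma_grid
    if (is.null(gammas)) {
      sc <- mean(vapply(proj, function(b) sum(b$QAk^2) / p, numeric(1)))
      gammas <- c(0, sc * 10^seq(-6, 3, length.out = 13))
    }
    err <- matrix(0, length(gammas), folds)
    for (f in seq_len(folds)) {
      v <- which(fold_id == f)
      tr <- which(fold_id != f)
      for (b in proj) {
        M0 <- crossprod(b$QAk[tr, , drop = FALSE])
        rhs <- crossprod(b$QAk[tr, , drop = FALSE], b$Qy[tr])
        Av <- b$QAk[v, , drop = FALSE]
        yv <- b$Qy[v]
        for (gi in seq_along(gammas)) {
          h <- drop(pinv(M0 + gammas[[gi]] * GtG, control$pinv_rtol) %*% rhs)
          err[gi, f] <- err[gi, f] + mean((yv - drop(Av %*% h))^2)
        }
      }
    }
    trace[[length(trace) + 1L]] <- tibble::tibble(
      order = p, gamma = gammas, cv_error = rowMeans(err))
  }
  cv_trace <- dplyr::bind_rows(trace)
  best <- min(cv_trace$cv_error)
  # ties measured relative to the larger of the minimum and the output
  # variance, so errors at machine-zero level compare as equal
  tie_scale <- max(best, stats::var(sigset$y))
  cand <- cv_trace[cv_trace$cv_error <=
    best + control$cv_tie_rtol * tie_scale, , drop = FALSE]
  cand <- cand[order(cand$gamma, cand$order), , drop = FALSE]
  structure(
    list(order = cand$order[[1]], gamma = cand$gamma[[1]], cv_trace = cv_trace),
    class = "obsp_cv"
  )
}

contiguous_folds <- function(n, folds) {
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(folds), times = sizes)
}

#' Amplitude frequency response of the estimated subsystems
#'
#' Zero-padded discrete Fourier transform amplitude of each estimated impulse
#' response, on a uniform grid from 0 to the Nyquist frequency. The gain at a
#' frequency tells how strongly variations of that input at that frequency are
#' expressed in the output component.
#'
#' @param result A [side_obsp()] fit.
#' @param n_freq Number of frequency points (`>= p`).
#' @return An object of class `"frequency_response"` with `freq` (Hz),
#'   `amplitude` (`n_freq x d`), `fs`, `names`.
#' @export
frequency_response <- function(result, n_freq = 256L) {
  stopifnot(inherits(result, "side_obsp"))
  if (!is.numeric(n_freq) || length(n_freq) != 1L || n_freq < result$p) {
    abort_sideobsp("`n_freq` must be a single integer >= the model order.",
      "invalid_parameter")
  }
  n_freq <- as.integer(n_freq)
  nfft <- 2L * (n_freq - 1L)
  amp <- apply(result$h, 2L, function(h) {
    abs(stats::fft(c(h, rep(0, nfft - length(h)))))[seq_len(n_freq)]
  })
  amp <- matrix(amp, n_freq, ncol(result$h),
    dimnames = list(NULL, colnames(result$h)))
  structure(
    list(
      freq = (seq_len(n_freq) - 1L) * result$fs / nfft,
      amplitude = amp,
      fs = result$fs,
      names = result$names
    ),
    class = "frequency_response"
  )
}

#' Fraction of impulse-response mass in the final taps
#'
#' Post-hoc order diagnostic: the share of `sum(|h|)` carried by the last 10%
#' of taps. Values near zero indicate the response has decayed within the
#' chosen order; large values suggest the order is too small.
#'
#' @param result A [side_obsp()] fit.
#' @return Named numeric vector, one value per input.
#' @export
tail_mass <- function(result) {
  stopifnot(inherits(result, "side_obsp"))
  p <- result$p
  tail_idx <- seq.int(max(1L, p - ceiling(0.1 * p) + 1L), p)
  apply(result$h, 2L, function(h) {
    tot <- sum(abs(h))
    if (tot == 0) 0 else sum(abs(h[tail_idx])) / tot
  })
}

#' @export
print.side_obsp <- function(x, ...) {
  cat(sprintf(
    "<side_obsp> %s ~ %s\n  order p = %d, gamma = %.4g, n = %d rows, R^2 = %.4f\n",
    x$names$target, paste(x$names$inputs, collapse = " + "),
    x$p, x$gamma, length(x$y_trim),
    1 - sum(x$residual^2) / sum((x$y_trim - mean(x$y_trim))^2)))
  invisible(x)
}

#' @export
print.obsp_cv <- function(x, ...) {
  cat(sprintf("<obsp_cv> selected order = %d, gamma = %.4g (%d grid points)\n",
    x$order, x$gamma, nrow(x$cv_trace)))
  invisible(x)
}
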
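#' Read synchronously sampled channels from a delimited-text file
#'
#' Expects a CSV with a header row, numeric channel columns, and optionally a
#' time column (`time` or `t`, numeric seconds). When a time column is
#' present the sampling is checked for monotonicity and regularity and `fs`
#' is inferred from the median step unless given.
#'
#' @param path CSV file path.
#' @param target Output channel name.
#' @param inputs Input channel names (default: all other numeric columns).
#' @param fs Sampling rate in Hz; inferred from the time column when `NULL`.
#' @param time Time column name (auto-detected when `NULL`).
#' @param na_action `"error"` (default) or `"interpolate"`: linear
#'   interpolation of interior gaps up to `max_gap` samples, logged.
#' @param max_gap Longest gap (samples) the interpolation may bridge.
#' @param irregular_tol Largest tolerated relative deviation of a time step
#'   from the median step.
#' @return A [signal_set()].
#' @export
read_signals <- function(path, target, inputs = NULL, fs = NULL, time = NULL,
                         na_action = c("error", "interpolate"), max_gap = 5L,
                         irregular_tol = 1e-3) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) {
    abort_sideobsp(sprintf("File not found: %s", path), "invalid_input")
  }
  df <- as.data.frame(readr::read_csv(path, show_col_types = FALSE,
    progress = FALSE))
  if (is.null(time)) {
    cand <- intersect(c("time", "t"), names(df))
    time <- if (length(cand)) cand[[1]] else NULL
  }
  if (!is.null(time)) {
    tv <- as.numeric(df[[time]])
    if (anyNA(tv) || any(diff(tv) <= 0)) {
      abort_sideobsp("Time column must be finite and strictly increasing.",
        "invalid_input")
    }
    dt <- diff(tv)
    med <- stats::median(dt)
    if (any(abs(dt - med) > irregular_tol * med)) {
      abort_sideobsp(sprintf(
        "Irregular sampling: time steps deviate from the median %.6g s by more than %.2g relative.",
        med, irregular_tol), "invalid_input")
    }
    if (is.null(fs)) fs <- 1 / med
  }
  if (is.null(fs)) fs <- 1
  if (is.null(inputs)) {
    inputs <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
      c(target, time))
  }
  for (nm in unique(c(inputs, target))) {
    if (!nm %in% names(df)) {
      abort_sideobsp(sprintf("Channel '%s' not found in %s.", nm, path),
        "invalid_input")
    }
    col <- as.numeric(df[[nm]])
    bad <- which(!is.finite(col))
    if (length(bad)) {
      if (na_action == "error") {
        abort_sideobsp(sprintf(
          "Non-finite value in channel '%s' at row %d (use na_action = \"interpolate\" for short gaps).",
          nm, bad[[1]]), "invalid_input")
      }
      col <- interpolate_gaps(col, nm, max_gap)
      message(sprintf("read_signals: interpolated %d sample(s) in '%s'.",
        length(bad), nm))
    }
    df[[nm]] <- col
  }
  signal_set(df, target = target, inputs = inputs, fs = fs, time = time)
}

interpolate_gaps <- function(col, nm, max_gap) {
  bad <- which(!is.finite(col))
  runs <- split(bad, cumsum(c(1, diff(bad) != 1)))
  for (r in runs) {
    if (length(r) > max_gap || min(r) == 1L || max(r) == length(col)) {
      abort_sideobsp(sprintf(
        "Gap of %d sample(s) in channel '%s' at rows %d-%d exceeds max_gap = %d or touches the record edge.",
        length(r), nm, min(r), max(r), max_gap), "invalid_input")
    }
  }
  ok <- which(is.finite(col))
  col[bad] <- stats::approx(ok, col[ok], xout = bad)$y
  col
}

#' Write a channel table to CSV
#'
#' Full-precision CSV writer (doubles round-trip losslessly through
#' [read_signals()]).
#'
#' @param data Data frame of channels.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_signals <- function(data, path) {
  readr::write_csv(as.data.frame(data), path, progress = FALSE)
  invisible(path)
}

#' Write decomposition results and a reproducibility manifest
#'
#' Emits four files into `dir`: `components.csv` (time-aligned partial
#' contributions named `<target>_<input>`, the residual, and the trimmed
#' observed target), `impulse_responses.csv`, `frequency_response.csv`, and
#' `manifest.json` (configuration, seeds, selected order/gamma, tolerances,
#' package and R versions, and the CV trace when present). Rewriting the same
#' fit produces bit-identical files.
#'
#' @param result A [side_obsp()] fit.
#' @param freq A [frequency_response()]; computed from `result` when `NULL`.
#' @param dir Output directory (created if needed).
#' @param config Optional named list echoed into the manifest.
#' @param seed Optional seed echoed into the manifest.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(result, freq = NULL, dir, config = NULL,
                          seed = NULL) {
  stopifnot(inherits(result, "side_obsp"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(freq)) {
    freq <- frequency_response(result, n_freq = max(256L, result$p))
  }
  target <- result$names$target
  comp <- as.data.frame(result$components)
  names(comp) <- paste0(target, "_", result$names$inputs)
  comp_df <- cbind(
    data.frame(time = result$time_trim),
    comp,
    residual = result$residual,
    stats::setNames(data.frame(result$y_trim), target)
  )
  f_comp <- file.path(dir, "components.csv")
  readr::write_csv(comp_df, f_comp, progress = FALSE)
  h_df <- cbind(
    data.frame(tap = seq_len(result$p) - 1L,
      lag_s = (seq_len(result$p) - 1L) / result$fs),
    as.data.frame(result$h)
  )
  f_h <- file.path(dir, "impulse_responses.csv")
  readr::write_csv(h_df, f_h, progress = FALSE)
  fr_df <- cbind(data.frame(freq_hz = freq$freq),
    as.data.frame(freq$amplitude))
  f_fr <- file.path(dir, "frequency_response.csv")
  readr::write_csv(fr_df, f_fr, progress = FALSE)
  manifest <- list(
    package = "sideobsp",
    version = as.character(utils::packageVersion("sideobsp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    target = target,
    inputs = result$names$inputs,
    fs = result$fs,
    order = result$p,
    gamma = result$gamma,
    projection = result$projection,
    seed = seed,
    tolerances = unclass(result$control),
    config = config,
    cv_trace = if (!is.null(result$cv_trace)) as.data.frame(result$cv_trace)
  )
  f_man <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  invisible(c(f_comp, f_h, f_fr, f_man))
}
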
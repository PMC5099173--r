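#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decomposition fit
#'
#' @param x A [side_obsp()] fit.
#' @param what One of `"components"` (long tibble of time, input, partial
#'   contribution), `"impulse_response"` (tap, lag, input, value), or
#'   `"cv_trace"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy side_obsp
#' @export
tidy.side_obsp <- function(x, what = c("components", "impulse_response",
                                       "cv_trace"), ...) {
  what <- match.arg(what)
  if (what == "components") {
    out <- tibble::as_tibble(as.data.frame(x$components))
    out$time <- x$time_trim
    out <- tidyr::pivot_longer(out, -"time",
      names_to = "input", values_to = "contribution")
    return(dplyr::arrange(out, .data$input, .data$time))
  }
  if (what == "impulse_response") {
    out <- tibble::as_tibble(as.data.frame(x$h))
    out$tap <- seq_len(x$p) - 1L
    out$lag <- out$tap / x$fs
    out <- tidyr::pivot_longer(out, -c("tap", "lag"),
      names_to = "input", values_to = "value")
    return(dplyr::arrange(out, .data$input, .data$tap))
  }
  if (is.null(x$cv_trace)) {
    return(tibble::tibble(order = integer(), gamma = double(),
      cv_error = double()))
  }
  x$cv_trace
}

#' One-row summary of a decomposition fit
#'
#' @param x A [side_obsp()] fit.
#' @param ... Unused.
#' @return A one-row tibble: `order`, `gamma`, `n`, `r_squared`,
#'   `residual_rms`, `tail_mass_max` (largest per-input fraction of
#'   impulse-response mass in the final 10% of taps — a large value flags a
#'   too-small order).
#' @method glance side_obsp
#' @export
glance.side_obsp <- function(x, ...) {
  tibble::tibble(
    order = x$p,
    gamma = x$gamma,
    n = length(x$y_trim),
    r_squared = 1 - sum(x$residual^2) /
      sum((x$y_trim - mean(x$y_trim))^2),
    residual_rms = sqrt(mean(x$residual^2)),
    tail_mass_max = max(tail_mass(x))
  )
}

#' @method tidy frequency_response
#' @export
tidy.frequency_response <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$amplitude))
  out$freq <- x$freq
  tidyr::pivot_longer(out, -"freq", names_to = "input",
    values_to = "amplitude")
}

#' @method tidy coupling_matrix
#' @export
tidy.coupling_matrix <- function(x, ...) {
  df <- as.data.frame(x$values)
  df$input <- rownames(x$values)
  out <- tidyr::pivot_longer(tibble::as_tibble(df), -"input",
    names_to = "component", values_to = "coupling")
  if (!is.null(x$significant)) {
    sig <- as.data.frame(x$significant)
    sig$input <- rownames(x$significant)
    sig <- tidyr::pivot_longer(tibble::as_tibble(sig), -"input",
      names_to = "component", values_to = "significant")
    out <- dplyr::left_join(out, sig, by = c("input", "component"))
  }
  out
}

#' Plot the partial contributions of a decomposition
#'
#' One facet per input channel showing its partial contribution to the
#' output, with the residual and the observed (trimmed) output in their own
#' facets.
#'
#' @param object A [side_obsp()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot side_obsp
#' @export
autoplot.side_obsp <- function(object, ...) {
  comp <- tidy(object, "components")
  extra <- tibble::tibble(
    time = rep(object$time_trim, 2L),
    input = rep(c(".observed", ".residual"), each = length(object$time_trim)),
    contribution = c(object$y_trim - mean(object$y_trim), object$residual)
  )
  df <- dplyr::bind_rows(comp, extra)
  ggplot2::ggplot(df,
    ggplot2::aes(x = .data$time, y = .data$contribution)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$input), scales = "free_y") +
    ggplot2::labs(
      x = "time (s)", y = "contribution",
      title = sprintf("Decomposition of %s", object$names$target)) +
    ggplot2::theme_minimal()
}

#' @method autoplot frequency_response
#' @export
autoplot.frequency_response <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
    ggplot2::aes(x = .data$freq, y = .data$amplitude,
      colour = .data$input)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "|H(f)|", colour = "input") +
    ggplot2::theme_minimal()
}

#' @method autoplot coupling_matrix
#' @export
autoplot.coupling_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
    ggplot2::aes(x = .data$component, y = .data$input,
      fill = .data$coupling)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("Coupling (%s)", object$method)) +
    ggplot2::theme_minimal()
}

#' Plot estimated impulse responses
#'
#' @param result A [side_obsp()] fit.
#' @param true_h Optional matrix of reference impulse responses (taps x
#'   inputs, same column order) overlaid as dashed lines.
#' @return A ggplot object.
#' @export
plot_impulse_responses <- function(result, true_h = NULL) {
  df <- tidy(result, "impulse_response")
  p <- ggplot2::ggplot(df,
    ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$input), scales = "free_y") +
    ggplot2::labs(x = "lag (s)", y = "impulse response") +
    ggplot2::theme_minimal()
  if (!is.null(true_h)) {
    ref <- tibble::as_tibble(as.data.frame(true_h))
    ref$lag <- (seq_len(nrow(true_h)) - 1L) / result$fs
    ref <- tidyr::pivot_longer(ref, -"lag", names_to = "input",
      values_to = "value")
    p <- p + ggplot2::geom_line(data = ref, linetype = "dashed",
      colour = "grey40")
  }
  p
}

#' @importFrom rlang .data
NULL
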
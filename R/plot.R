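#' Plot a simulated or deterministic trajectory
#'
#' One line per range state over time; frequencies additionally get a fixed
#' `[0, 1]` scale.
#'
#' @param object An `sse_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sse_trajectory <- function(object, ...) {
  kind <- attr(object, "kind")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(as.data.frame(object)),
    -"time", names_to = "state", values_to = "value"
  )
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$time, y = .data$value, colour = .data$state)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time",
      y = if (identical(kind, "frequencies")) "state frequency" else "state count",
      colour = "range state"
    ) +
    ggplot2::theme_minimal()
  if (identical(kind, "frequencies")) {
    p <- p + ggplot2::coord_cartesian(ylim = c(0, 1))
  }
  p
}

#' Plot an ensemble mean path with terminal intervals
#'
#' Shows the per-time mean trajectory (when replicates share a grid) and the
#' terminal 95% confidence intervals per state.
#'
#' @param object An `sse_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sse_ensemble <- function(object, ...) {
  if (!is.null(object$mean_path)) {
    p <- autoplot.sse_trajectory(object$mean_path)
  } else {
    p <- ggplot2::ggplot() + ggplot2::theme_minimal() +
      ggplot2::labs(x = "time",
                    y = if (identical(object$kind, "frequencies"))
                      "state frequency" else "state count")
  }
  t_end <- if (!is.null(object$mean_path)) max(object$mean_path$time) else NA_real_
  p + ggplot2::geom_pointrange(
    data = dplyr::mutate(object$summary, time = t_end),
    ggplot2::aes(x = .data$time, y = .data$mean, ymin = .data$lower,
                 ymax = .data$upper, colour = .data$state)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
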
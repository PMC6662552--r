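# ggplot2 displays for the main result types.

#' Plot the selection response across generations
#'
#' Group means of the manipulation score per selection line and generation
#' with their bootstrap confidence intervals, in the conventional
#' lines-by-generation layout.
#'
#' @param x A `response_summary` (see [selection_response_summary()]), a
#'   score table, or a `selection_experiment`.
#' @param ... Passed to [selection_response_summary()] when `x` still needs
#'   summarising.
#' @return A ggplot object.
#' @export
plot_selection_response <- function(x, ...) {
  summ <- if (inherits(x, "response_summary")) {
    x
  } else if (inherits(x, "selection_experiment")) {
    selection_response_summary(x$scores |> filter(.data$infected), ...)
  } else {
    selection_response_summary(x, ...)
  }
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = .data$generation, y = .data$mean,
                               colour = .data$line, group = .data$line)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      position = ggplot2::position_dodge(width = 0.2)
    ) +
    ggplot2::labs(x = "Generation", y = "Host manipulation (post - pre activity)",
                  colour = "Selection line") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.response_summary <- function(object, ...) {
  plot_selection_response(object, ...)
}

#' @export
autoplot.selection_experiment <- function(object, ...) {
  plot_selection_response(object, ...)
}

#' @export
autoplot.track_result <- function(object, ...) {
  pos <- object$positions |> filter(.data$detected)
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$t_s), size = 1.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "t (s)",
                  title = sprintf("activity = %.3f over %d intervals",
                                  object$activity, object$n_intervals)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.selection_pool <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   fill = .data$selected)) +
    ggplot2::geom_histogram(bins = 20, alpha = 0.8,
                            position = "identity") +
    ggplot2::labs(x = "Manipulation score", fill = "Selected") +
    ggplot2::theme_minimal()
}
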
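#' Plot a sweep result
#'
#' For window and feature sweeps, mean accuracy against window size (ribbon =
#' min-max across repetitions where available); for the coordinate-selection
#' experiment, mean accuracy per coordinate set and classifier.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  kind <- attr(object, "kind")
  if (kind == "coordinate_selection") {
    return(
      ggplot2::ggplot(object, ggplot2::aes(x = .data$coordinate_set,
                                           y = .data$mean,
                                           fill = .data$classifier)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::labs(x = "coordinate set", y = "mean accuracy",
                      title = sprintf("Coordinate selection (window size %d)",
                                      object$window_size[1])) +
        ggplot2::ylim(0, 1)
    )
  }
  df <- if (kind == "window_sweep") {
    dplyr::mutate(dplyr::filter(object, .data$metric == "accuracy"),
                  series = .data$feature_set)
  } else {
    dplyr::mutate(object, series = paste(.data$feature, .data$classifier))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_size, y = .data$mean,
                                   colour = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max,
                                      fill = .data$series),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "window size N", y = "accuracy", colour = NULL,
                  fill = NULL)
}

#' Plot the palm trajectory of a recording
#'
#' Palm-centre position channels against time; the lateral (x) channel shows
#' the hold-then-push task with the superimposed tremor oscillation.
#'
#' @param object A [tremor_recording()].
#' @param channels Channels to draw (default the palm position triplet).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tremor_recording <- function(object, channels = palm_channels(), ...) {
  df <- tibble::tibble(time = (seq_len(nrow(object)) - 1) / sample_rate(object))
  df <- dplyr::bind_cols(df, tibble::as_tibble(as.data.frame(object)[channels]))
  long <- tidyr::pivot_longer(df, -"time", names_to = "channel")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "time (s)", y = "position (mm)",
      title = sprintf("patient %s, %s hand, tremor level %d",
                      attr(object, "patient_id"), attr(object, "hand"),
                      tremor_level(object))
    )
}
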
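#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot region error summaries
#'
#' Bar chart of the average error by body region with STD whiskers.
#'
#' @param object A `region_error_summary` from [region_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_error_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region, y = .data$ae_mm)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$ae_mm - .data$std_mm),
                   ymax = .data$ae_mm + .data$std_mm),
      width = 0.2) +
    ggplot2::labs(x = NULL, y = "average error (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a fusion sweep
#'
#' Average error per body region across the levels of the swept axis
#' (variant, searching area or number of sensors).
#'
#' @param object A `fusion_sweep` from [sweep_eps()], [sweep_sensors()] or
#'   [compare_variants()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fusion_sweep <- function(object, ...) {
  axis <- attr(object, "axis")
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data[[axis]]), y = .data$ae_mm, fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = axis, y = "average error (mm)", fill = "region") +
    ggplot2::theme_minimal()
  p
}

#' Plot a skeleton pose or merged track frame
#'
#' Draws the skeleton (joints and bones) of one frame, projected on two of
#' the three axes.
#'
#' @param track A truth or merged track tibble.
#' @param frame Frame index to draw (default: first).
#' @param axes Character vector of length 2 among `"x"`, `"y"`, `"z"`.
#' @return A ggplot object.
#' @export
plot_skeleton <- function(track, frame = NULL, axes = c("y", "z")) {
  stopifnot(length(axes) == 2, all(axes %in% c("x", "y", "z")))
  if (is.null(frame)) frame <- min(track$frame_index)
  sub <- track[track$frame_index == frame, ]
  cols <- paste0(axes, "_mm")
  bones <- bone_table()
  seg <- dplyr::inner_join(
    dplyr::rename(bones, joint = "from"), sub, by = "joint") |>
    dplyr::select(to = "to", xend_from = dplyr::all_of(cols[1]),
                  yend_from = dplyr::all_of(cols[2])) |>
    dplyr::rename(joint = "to") |>
    dplyr::inner_join(sub, by = "joint")
  ggplot2::ggplot(sub, ggplot2::aes(x = .data[[cols[1]]],
                                    y = .data[[cols[2]]])) +
    ggplot2::geom_segment(data = seg, ggplot2::aes(
      x = .data$xend_from, y = .data$yend_from,
      xend = .data[[cols[1]]], yend = .data[[cols[2]]]),
      color = "grey50") +
    ggplot2::geom_point(color = "firebrick", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = cols[1], y = cols[2]) +
    ggplot2::theme_minimal()
}
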
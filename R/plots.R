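# ggplot2 views of the main result types.

#' Plot a dive profile with its bottom phase
#'
#' Depth against time with the delimited bottom phase of each dive shaded.
#'
#' @param depth corrected depth tibble `time`, `depth`.
#' @param dives dive table from [delimit_bottom()].
#' @return A ggplot object.
#' @export
plot_dive_profile <- function(depth, dives = NULL) {
  p <- ggplot2::ggplot(depth, ggplot2::aes(x = .data$time, y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Time (s)", y = "Depth (m)") +
    ggplot2::theme_minimal()
  if (!is.null(dives) && nrow(dives) > 0) {
    shade <- dives |>
      filter(!is.na(.data$descent_end)) |>
      mutate(xmin = depth$time[.data$descent_end],
             xmax = depth$time[.data$ascent_start])
    if (nrow(shade) > 0) {
      p <- p + ggplot2::geom_rect(
        data = shade, inherit.aes = FALSE, alpha = 0.2, fill = "steelblue",
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf)
      )
    }
  }
  p
}

#' Map and profile views of a 3D track
#'
#' @param track a `track3d` tibble.
#' @param view `"map"` (east/north, coloured by depth) or `"profile"`
#'   (along-track distance vs depth).
#' @return A ggplot object.
#' @export
plot_track3d <- function(track, view = c("map", "profile")) {
  view <- match.arg(view)
  if (view == "map") {
    ggplot2::ggplot(track, ggplot2::aes(x = .data$east, y = .data$north,
                                        colour = -.data$z)) +
      ggplot2::geom_path() +
      ggplot2::coord_equal() +
      ggplot2::scale_colour_viridis_c(name = "Depth (m)") +
      ggplot2::labs(x = "East (m)", y = "North (m)") +
      ggplot2::theme_minimal()
  } else {
    d <- track |>
      mutate(s = c(0, cumsum(sqrt(diff(.data$east)^2 + diff(.data$north)^2))))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$s, y = -.data$z)) +
      ggplot2::geom_path() +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(x = "Horizontal distance (m)", y = "Depth (m)") +
      ggplot2::theme_minimal()
  }
}

#' Distribution of the first-main-component dispersion
#'
#' Histogram of the per-dive MC1 dispersion (share of the total positional
#' variance along the dominant direction; 1/3 = isotropic, 1 = straight
#' line), with the sample mean marked.
#'
#' @param metrics per-dive metrics table with `mc1_dispersion`.
#' @return A ggplot object.
#' @export
plot_mc1_dispersion <- function(metrics) {
  m <- mean(metrics$mc1_dispersion, na.rm = TRUE)
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$mc1_dispersion)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = m, linewidth = 0.8) +
    ggplot2::labs(x = "MC1 dispersion (fraction of total)", y = "Dives") +
    ggplot2::theme_minimal()
}
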
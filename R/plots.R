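#' Plot a simulated nucleus (2D projection)
#'
#' Projects the foci onto the XY plane, coloured by time zone, with the
#' nuclear outline — the view a single confocal section approximates.
#'
#' @param object A `foci_set`.
#' @param zones Optional subset of zones to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot foci_set
#' @export
autoplot.foci_set <- function(object, zones = NULL, ...) {
  nuc <- attr(object, "nucleus")
  df <- if (is.null(zones)) object else zone_subset(object, zones)
  r <- nuc$nucleus_diameter_um * 1000 / 2
  circ <- tibble(
    x = r * cos(seq(0, 2 * pi, length.out = 200)),
    y = r * sin(seq(0, 2 * pi, length.out = 200))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x_nm, .data$y_nm)) +
    ggplot2::geom_path(data = circ, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$zone)),
                        size = 1, alpha = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", colour = "zone",
                  title = sprintf("%s model, %d foci",
                                  attr(object, "model") %||% "",
                                  nrow(df))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a timing profile with called domains
#'
#' @param p A `timing_profile`.
#' @param domains Optional domains tibble from [call_domains()]; boundaries
#'   and apexes are overlaid when given.
#' @return A ggplot object.
#' @export
plot_timing_domains <- function(p, domains = NULL) {
  g <- ggplot2::ggplot(p, ggplot2::aes((.data$start + .data$end) / 2e6,
                                       .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "position (Mbp)", y = "timing signal") +
    ggplot2::theme_minimal()
  if (!is.null(domains) && nrow(domains)) {
    g <- g +
      ggplot2::geom_vline(xintercept = unique(c(domains$start,
                                                domains$end)) / 1e6,
                          linetype = "dashed", colour = "grey50") +
      ggplot2::geom_point(
        data = domains,
        ggplot2::aes(.data$apex_position / 1e6, .data$apex_value),
        colour = "firebrick", inherit.aes = FALSE
      )
  }
  g
}

#' Plot labeled fiber tracks
#'
#' Draws each fiber as a horizontal line of its labeled tracks, channel 1
#' (first pulse) in red and channel 2 (second pulse) in green, the
#' convention of the original micrographs.
#'
#' @param fibers A `fiber_set` or tracks tibble.
#' @param fiber_ids Optional subset of fibers to show.
#' @return A ggplot object.
#' @export
plot_fibers <- function(fibers, fiber_ids = NULL) {
  df <- as_tibble(fibers)
  if (!is.null(fiber_ids)) df <- df[df$fiber_id %in% fiber_ids, ]
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_um, xend = .data$end_um,
                   y = factor(.data$fiber_id), yend = factor(.data$fiber_id),
                   colour = factor(.data$channel)),
      linewidth = 3
    ) +
    ggplot2::scale_colour_manual(values = c(`1` = "firebrick",
                                            `2` = "forestgreen"),
                                 labels = c("pulse 1", "pulse 2")) +
    ggplot2::labs(x = "position (µm)", y = "fiber", colour = "channel") +
    ggplot2::theme_minimal()
}

#' Plot a distribution profile as a frequency histogram
#'
#' @param object A `distribution_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distribution_profile
#' @export
autoplot.distribution_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                               y = .data$frequency)) +
    ggplot2::geom_col(width = object$bin_end[1] - object$bin_start[1],
                      fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "DNA content (kbp)", y = "frequency") +
    ggplot2::theme_minimal()
}
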
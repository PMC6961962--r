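.nc_palette <- c(blue = "#4477AA", green = "#66A61E", brown = "#8C510A",
                 murky = "#5E4B3C")

#' Rose diagram of change-vector directions
#'
#' Circular histogram of direction angles (0 degrees = pure TP increase,
#' 90 degrees = pure color increase).
#'
#' @param x A tibble from [rose_bins()], an `nc_vector_summary`, or a
#'   vector of angles in degrees.
#' @param n_bins Bin count when `x` is a vector of angles.
#' @return A ggplot object.
#' @export
plot_rose <- function(x, n_bins = 16) {
  bins <- if (inherits(x, "nc_vector_summary")) x$rose
          else if (is.data.frame(x)) x
          else rose_bins(x, n_bins)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = 360 / nrow(bins), fill = "#4477AA",
                      colour = "grey20", linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = "Direction (degrees from +TP axis)", y = "Lakes") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.nc_vector_summary <- function(object, ...) plot_rose(object)

#' Plot between-survey changes in class proportions
#'
#' Point-and-interval display of the percentage-point change per class
#' (and per scope when several are present); intervals crossing zero are
#' not significant.
#'
#' @param change A tibble from [change_analysis()].
#' @return A ggplot object.
#' @export
plot_change_estimates <- function(change) {
  p <- ggplot2::ggplot(change,
                       ggplot2::aes(x = .data$category, y = .data$delta,
                                    colour = .data$category)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_colour_manual(values = .nc_palette, guide = "none") +
    ggplot2::labs(x = NULL, y = "Change in share of lakes (points)") +
    ggplot2::theme_minimal()
  if (length(unique(change$scope)) > 1) {
    p <- p + ggplot2::facet_wrap(~scope)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.nc_transition <- function(object, ...) {
  d <- tidy.nc_transition(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$destination, y = .data$origin,
                                  fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#4477AA",
                                 guide = "none") +
    ggplot2::labs(x = "Class in second survey",
                  y = "Class in first survey") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.nc_nmds <- function(object, labels = NULL, ...) {
  d <- object$points
  if (!is.null(labels)) d$label <- labels
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::labs(
      subtitle = sprintf("stress-1 = %.3f", object$stress),
      x = "NMDS 1", y = "NMDS 2") +
    ggplot2::theme_minimal()
  if (is.null(labels)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label)) +
      ggplot2::scale_colour_manual(values = .nc_palette, name = NULL)
  }
}

#' Scatter of lakes in (TP, color) space
#'
#' @param data A classified survey tibble.
#' @param thresholds Classification thresholds drawn as reference lines.
#' @return A ggplot object (log-scaled axes).
#' @export
plot_nutrient_color <- function(data, thresholds = nc_thresholds()) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$tp, y = .data$color,
                                     colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = thresholds$tp, linetype = 2) +
    ggplot2::geom_hline(yintercept = thresholds$color, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = .nc_palette, name = NULL) +
    ggplot2::labs(x = "Total phosphorus (ug/L)", y = "True color (PCU)") +
    ggplot2::theme_minimal()
}
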
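#' Universal-semicircle layer for phasor plots
#'
#' @param colour,linetype Passed to [ggplot2::geom_path()].
#' @return A ggplot2 layer drawing the semicircle from (0, 0) to (1, 0).
#' @export
semicircle_layer <- function(colour = "grey40", linetype = "dashed") {
  theta <- seq(0, pi, length.out = 200)
  ggplot2::geom_path(
    data = data.frame(g = 0.5 + 0.5 * cos(theta), s = 0.5 * sin(theta)),
    ggplot2::aes(x = .data$g, y = .data$s),
    colour = colour, linetype = linetype, inherit.aes = FALSE
  )
}

#' Phasor-plot density of a field
#'
#' @param object A `phasor_field`.
#' @param bins Number of 2-D bins (default 120).
#' @param ... Unused.
#' @return A ggplot object: 2-D density of the defined pixels with the
#'   universal semicircle overlaid.
#' @export
autoplot.phasor_field <- function(object, bins = 120, ...) {
  df <- tidy.phasor_field(object)
  df <- df[df$defined, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$s)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    semicircle_layer() +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 0.6)) +
    ggplot2::labs(x = "g", y = "s", fill = "pixels",
                  title = sprintf("Phasor plot (harmonic %d)", object$harmonic)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.phasor_field
#' @export
plot.phasor_field <- function(x, ...) print(autoplot.phasor_field(x, ...))

#' Heatmap of a phasor-plot occupancy histogram
#'
#' @param object A `phasor_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phasor_histogram <- function(object, ...) {
  gx <- (object$g_edges[-1L] + object$g_edges[-length(object$g_edges)]) / 2
  sx <- (object$s_edges[-1L] + object$s_edges[-length(object$s_edges)]) / 2
  df <- expand.grid(g = gx, s = sx)
  df$count <- as.vector(object$counts)
  ggplot2::ggplot(df[df$count > 0, ],
                  ggplot2::aes(x = .data$g, y = .data$s, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    semicircle_layer() +
    ggplot2::coord_fixed(xlim = range(object$g_edges),
                         ylim = range(object$s_edges)) +
    ggplot2::labs(x = "g", y = "s", fill = "pixels") +
    ggplot2::theme_minimal()
}

#' Rendered free/bound-NADH fraction map
#'
#' @param object A `fraction_map`.
#' @param ... Unused.
#' @return A ggplot object: the per-pixel free fraction with the cursor's
#'   colour ramp (free end first), undefined pixels black.
#' @export
autoplot.fraction_map <- function(object, ...) {
  nr <- nrow(object$fraction)
  nc <- ncol(object$fraction)
  df <- data.frame(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    fraction = as.vector(object$fraction)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$fraction)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = rev(object$cursor$colormap),
                                  limits = c(0, 1), na.value = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "free\nfraction") +
    ggplot2::theme_void()
}

#' @rdname autoplot.fraction_map
#' @export
plot.fraction_map <- function(x, ...) print(autoplot.fraction_map(x, ...))

#' Cell-phasor scatter plot
#'
#' The population view: one point per segmented cell at its average
#' phasor, coloured by group, with the universal semicircle for scale.
#'
#' @param records A cell-phasor record tibble (see [cell_phasors()]).
#' @param zoom Zoom to the data range (default `TRUE`) instead of the
#'   full semicircle window.
#' @return A ggplot object.
#' @export
plot_cell_phasors <- function(records, zoom = TRUE) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$g_mean, y = .data$s_mean,
                                    colour = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    semicircle_layer() +
    ggplot2::labs(x = "g", y = "s", colour = "group") +
    ggplot2::theme_minimal()
  if (zoom) {
    pad <- 0.03
    p <- p + ggplot2::coord_fixed(
      xlim = range(records$g_mean) + c(-pad, pad),
      ylim = range(records$s_mean) + c(-pad, pad)
    )
  } else {
    p <- p + ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 0.6))
  }
  p
}

#' Frame-stability trend plot
#'
#' @param object A `frame_stability` result.
#' @param ... Unused.
#' @return A ggplot object: per-ROI cell-phasor g over frame blocks with
#'   the fitted linear trend.
#' @export
autoplot.frame_stability <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$frame_group, y = .data$g_mean,
                               colour = factor(.data$roi_label))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.5) +
    ggplot2::labs(x = sprintf("frame block (%d frames each)",
                              object$frame_group_size),
                  y = "cell phasor g", colour = "ROI") +
    ggplot2::theme_minimal()
}
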
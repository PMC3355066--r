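# ggplot2 visualizations for arrays, fits and reports.

cell_polygon_data <- function(array) {
  pos <- vertex_matrix(array)
  purrr::map_dfr(seq_len(nrow(array$cells)), function(k) {
    p <- unwrap_loop(array, array$cells$vertices[[k]], pos)
    tibble::tibble(cell = array$cells$id[[k]], x = p[, 1], y = p[, 2],
                   boundary = array$cells$boundary[[k]])
  })
}

edge_segment_data <- function(array) {
  pos <- vertex_matrix(array)
  i <- match(array$edges$v1, array$vertices$id)
  j <- match(array$edges$v2, array$vertices$id)
  d <- displacements(pos, i, j, array$box)
  tibble::tibble(edge = array$edges$id,
                 x = pos[i, 1], y = pos[i, 2],
                 xend = pos[i, 1] + d[, 1], yend = pos[i, 2] + d[, 2])
}

#' Plot a cell array
#'
#' Draws the polygonal tiling; optionally fills cells by a per-cell value
#' or colors interfaces by a per-edge value (e.g. inferred tension).
#'
#' @param object A [cell_array()].
#' @param fill Optional tibble with columns `cell`, `value` for cell fill.
#' @param edge_color Optional tibble with columns `edge`, `value` for edge
#'   coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cell_array
#' @export
autoplot.cell_array <- function(object, fill = NULL, edge_color = NULL, ...) {
  poly <- cell_polygon_data(object)
  p <- ggplot2::ggplot()
  if (!is.null(fill)) {
    poly$value <- fill$value[match(poly$cell, fill$cell)]
    p <- p + ggplot2::geom_polygon(
      data = poly,
      ggplot2::aes(.data$x, .data$y, group = .data$cell, fill = .data$value),
      color = "grey30", linewidth = 0.2
    ) + ggplot2::scale_fill_viridis_c()
  } else {
    p <- p + ggplot2::geom_polygon(
      data = poly,
      ggplot2::aes(.data$x, .data$y, group = .data$cell),
      fill = "grey95", color = "grey30", linewidth = 0.2
    )
  }
  if (!is.null(edge_color)) {
    seg <- edge_segment_data(object)
    seg$value <- edge_color$value[match(seg$edge, edge_color$edge)]
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(.data$x, .data$y, xend = .data$xend, yend = .data$yend,
                   color = .data$value),
      linewidth = 0.8
    ) + ggplot2::scale_color_viridis_c(option = "plasma")
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a recovery scatter
#'
#' True versus inferred tension (both rescaled to mean 1) with the identity
#' line and the Pearson correlation in the subtitle.
#'
#' @param scatter Output of [recovery_scatter()].
#' @return A ggplot object.
#' @export
plot_recovery <- function(scatter) {
  ggplot2::ggplot(scatter$pairs, ggplot2::aes(.data$true, .data$inferred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "true tension", y = "inferred tension",
                  subtitle = sprintf("Pearson r = %.3f (n = %d)", scatter$r, nrow(scatter$pairs))) +
    ggplot2::theme_minimal()
}

#' @rdname sensitivity_report
#' @param object A `sensitivity_report`.
#' @param ... Unused.
#' @method autoplot sensitivity_report
#' @export
autoplot.sensitivity_report <- function(object, ...) {
  df <- tidy.sensitivity_report(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$singular_value, fill = .data$problem)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "singular value of the error-response operator", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a noise-robustness curve
#'
#' Mean recovered correlation against noise level with one standard
#' deviation ribbon across replicates.
#'
#' @param curve Output of [noise_curve()].
#' @return A ggplot object.
#' @export
plot_noise_curve <- function(curve) {
  s <- dplyr::summarise(dplyr::group_by(curve, .data$noise_level),
                        mean_r = mean(.data$r), sd_r = stats::sd(.data$r), .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(.data$noise_level, .data$mean_r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                                      ymax = .data$mean_r + .data$sd_r), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "vertex noise (r.m.s. / mean edge length)",
                  y = "Pearson r (true vs inferred tension)") +
    ggplot2::theme_minimal()
}
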
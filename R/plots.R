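#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a deviance partition as a stacked share bar
#'
#' @param object A `deviance_partition`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.deviance_partition <- function(object, ...) {
  tab <- dplyr::filter(object$table, .data$component != "residual")
  ggplot2::ggplot(tab, ggplot2::aes(
    x = object$engine, y = .data$share_explained, fill = .data$component
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "% of explained deviance", fill = "component",
      title = "Deviance attributed to SDM, GCM and RCP choices"
    ) +
    ggplot2::theme_minimal()
}

#' Map one climate variable on the grid
#'
#' @param layers A `climate_layers` tibble.
#' @param variable One of the four climate variable names.
#' @return A ggplot raster-style map.
#' @export
plot_climate <- function(layers, variable = "mean_temp") {
  variable <- match.arg(variable, climate_vars)
  ggplot2::ggplot(layers, ggplot2::aes(
    x = .data$col, y = .data$row, fill = .data[[variable]]
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = variable) +
    ggplot2::theme_minimal()
}

#' Map per-pixel component shares
#'
#' @param pixel_partition A [partition_per_pixel()] table.
#' @param grid The [make_grid()] the cells refer to.
#' @param component Which component's share to map (default `"sdm"`).
#' @return A ggplot faceted by any extra grouping columns present.
#' @export
plot_partition_map <- function(pixel_partition, grid, component = "sdm") {
  rows <- dplyr::filter(pixel_partition, .data$component == !!component)
  rows <- dplyr::left_join(rows, cell_coords(grid), by = "cell")
  p <- ggplot2::ggplot(rows, ggplot2::aes(
    x = .data$col, y = .data$row, fill = .data$share_explained
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "column", y = "row", fill = "% explained",
      title = sprintf("Relative influence of %s", toupper(component))
    ) +
    ggplot2::theme_minimal()
  if ("taxon" %in% names(rows)) p <- p + ggplot2::facet_wrap(~taxon)
  p
}

#' Plot component shares across range-size bins
#'
#' @param bin_partition A [partition_by_range_bin()] table.
#' @return A ggplot of share-of-explained deviance per component against
#'   the range-size bin.
#' @export
plot_range_bin_shares <- function(bin_partition) {
  rows <- dplyr::filter(bin_partition, .data$component != "residual")
  ggplot2::ggplot(rows, ggplot2::aes(
    x = .data$bin, y = .data$share_explained,
    colour = .data$component, group = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "range-size bin (small to large, log scale)",
      y = "% of explained deviance", colour = "component"
    ) +
    ggplot2::theme_minimal()
}
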
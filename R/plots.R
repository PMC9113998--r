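#' Plot a grid
#'
#' `autoplot()` renders any [geo_grid()] as a ggplot2 raster map (cell
#' centres in degrees, `NA` cells blank); for a `travel_time_result` the
#' minutes grid is drawn with the facility cells overlaid.
#'
#' @param object A [geo_grid()] or `travel_time_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.geo_grid <- function(object, ...) {
  df <- tidy.geo_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' @rdname autoplot.geo_grid
#' @export
autoplot.travel_time_result <- function(object, ...) {
  g <- object$minutes
  src <- tibble::tibble(
    lon = cell_centre_lon(g, object$source_cells$col),
    lat = cell_centre_lat(g, object$source_cells$row)
  )
  autoplot.geo_grid(g) +
    ggplot2::geom_point(data = src,
                        ggplot2::aes(x = .data$lon, y = .data$lat),
                        inherit.aes = FALSE, shape = 3, colour = "red") +
    ggplot2::labs(fill = "minutes")
}

#' @rdname autoplot.geo_grid
#' @param grid A [geo_grid()].
#' @export
plot_travel_time <- function(grid, ...) {
  autoplot.geo_grid(grid) + ggplot2::labs(fill = "minutes")
}
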
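# ggplot2 autoplot methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a grid map as a periodic raster
#' @param object A `grid_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_map <- function(object, ...) {
  df <- as_tibble.grid_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = object$unit)
}

#' Plot per-carbon order distributions
#' @param object An `order_distribution`.
#' @param ... Unused.
#' @return A ggplot (carbon on x, -S_CD on y, mass as fill).
#' @export
autoplot.order_distribution <- function(object, ...) {
  df <- as_tibble.order_distribution(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$carbon, y = .data$scd,
                                   fill = .data$mass)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "acyl carbon", y = expression(-S[CD]), fill = "mass")
}

#' Plot the interleaflet joint order histogram
#' @param object A `joint_order_histogram`.
#' @param ... Unused.
#' @return A ggplot; diagonal mass indicates leaflet registration.
#' @export
autoplot.joint_order_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$upper, y = .data$lower,
                                       fill = .data$mass)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "upper-leaflet order", y = "lower-leaflet order",
                  subtitle = sprintf("Pearson r = %.3f, band mass = %.3f",
                                     attr(object, "pearson_r"),
                                     attr(object, "band_mass")))
}

#' Plot a region map
#' @param object A `region_map`.
#' @param ... Unused.
#' @return A ggplot with the three classes and the boundary overlaid.
#' @export
autoplot.region_map <- function(object, ...) {
  df <- as_tibble.region_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = df[df$boundary, ], size = 0.3,
                        colour = "black") +
    ggplot2::scale_fill_manual(values = c(core = "#1f78b4",
                                          ordered = "#ffd92f",
                                          disordered = "#e31a1c"),
                               na.value = "grey80") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' Plot domain area versus time
#' @param object A `domain_area_series` from [track_domain_area()].
#' @param ... Unused.
#' @return A ggplot of per-class area against window mid-time.
#' @export
autoplot.domain_area_series <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("disordered", "ordered", "core"),
                            names_to = "class", values_to = "area")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_mid, y = .data$area,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = expression(area ~ (nm^2)))
}

#' Export a grid map as a CSV matrix plus a JSON header
#' @param map A `grid_map`.
#' @param path CSV path; the header (cell size, box, unit) goes to a
#'   `.json` side-car.
#' @return `path`, invisibly.
#' @export
write_grid_map <- function(map, path) {
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(cell_nm = map$cell, box_nm = map$box,
                            unit = map$unit, nx = nrow(map$values),
                            ny = ncol(map$values)),
                       sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
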
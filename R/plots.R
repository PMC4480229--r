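# Optional ggplot2 renderings of scenarios and stranding densities.

#' Map a scenario with optional colony positions
#'
#' @param scenario a [make_scenario()] result.
#' @param population optional `drift_population` to overlay.
#' @param run optional `drift_run`; stranding locations are overlaid.
#' @return a ggplot object.
#' @export
plot_scenario <- function(scenario, population = NULL, run = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_scenario needs the ggplot2 package")
  g <- scenario$grid
  df <- expand.grid(lon = g$lon, lat = g$lat)
  df$depth <- as.vector(t(scenario$bathymetry))
  df$land <- as.vector(t(scenario$land_mask))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = lon, y = lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = ifelse(land, NA, depth))) +
    ggplot2::scale_fill_viridis_c(name = "depth (m)", direction = -1,
                                  na.value = "grey30") +
    ggplot2::coord_fixed(1 / cos(mean(g$lat) * pi / 180)) +
    ggplot2::theme_minimal()
  for (s in scenario$beaches)
    p <- p + ggplot2::annotate("path", x = s$vertices[, 1],
                               y = s$vertices[, 2], colour = "orange",
                               linewidth = 1)
  if (!is.null(population))
    p <- p + ggplot2::annotate("point", x = population$lon,
                               y = population$lat, size = 0.3,
                               colour = "red")
  if (!is.null(run) && nrow(run$strandings))
    p <- p + ggplot2::annotate("point", x = run$strandings$lon,
                               y = run$strandings$lat, size = 0.5,
                               colour = "black")
  p
}

#' Bar chart of stranding densities per beach, west to east
#'
#' @param table a [density_per_100m()] table, or a [compare_patterns()]
#'   result (simulated and observed side by side).
#' @return a ggplot object.
#' @export
plot_stranding_density <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_stranding_density needs the ggplot2 package")
  if (inherits(table, "pattern_comparison")) {
    tb <- table$table
    df <- data.frame(
      beach = factor(rep(tb$beach_id, 2), levels = tb$beach_id),
      density = c(tb$sim_density, tb$obs_density),
      source = rep(c("simulated", "observed"), each = nrow(tb)))
    return(ggplot2::ggplot(df, ggplot2::aes(x = beach, y = density,
                                            fill = source)) +
             ggplot2::geom_col(position = "dodge") +
             ggplot2::labs(y = "colonies per 100 m of coastline",
                           x = "beach (west to east)") +
             ggplot2::theme_minimal())
  }
  df <- data.frame(beach = factor(table$beach_id, levels = table$beach_id),
                   density = table$density_per_100m)
  ggplot2::ggplot(df, ggplot2::aes(x = beach, y = density)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(y = "colonies per 100 m of coastline",
                  x = "beach (west to east)") +
    ggplot2::theme_minimal()
}
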
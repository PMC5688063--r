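#' Plot a deficit table as a time series with its confidence band
#'
#' The mean-level deficit (as a fraction of the potential) is drawn as a
#' line; when the `q05` and `q95` levels are present they form a ribbon.
#'
#' @param object A `deficit_table` (from [run_ensemble()]).
#' @param fraction Plot the deficit fraction (default) or, if `FALSE`,
#'   the deficit total in Pg C.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deficit_table <- function(object, fraction = TRUE, ...) {
  var <- if (fraction) "deficit_fraction" else "agb_def_pg"
  wide <- tidyr::pivot_wider(object[c("year", "level", var)],
                             names_from = "level",
                             values_from = dplyr::all_of(var))
  p <- ggplot2::ggplot(wide, ggplot2::aes(x = .data$year))
  if (all(c("q05", "q95") %in% names(wide))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
      fill = "darkgreen", alpha = 0.25)
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.8) +
    ggplot2::labs(
      x = "Year",
      y = if (fraction) "Deficit / potential" else "Deficit (Pg C)") +
    ggplot2::theme_minimal()
}

#' Map a raster tibble
#'
#' Simple lat/lon tile map of one value column; the intact mask can be
#' greyed out.
#'
#' @param field Raster tibble with `lat`, `lon` and a value column.
#' @param value Value column to map (default `"value"`).
#' @param diverging Use a diverging palette centred on zero, as suits a
#'   deficit or change map (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_deficit_map <- function(field, value = "value", diverging = TRUE) {
  stopifnot(all(c("lat", "lon", value) %in% names(field)))
  p <- ggplot2::ggplot(field,
                       ggplot2::aes(x = .data$lon, y = .data$lat,
                                    fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
  if (diverging) {
    p <- p + ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                           high = "firebrick", midpoint = 0,
                                           na.value = "grey85")
  } else {
    p <- p + ggplot2::scale_fill_viridis_c(na.value = "grey85")
  }
  p
}

#' Plot observed and potential basin totals through time
#'
#' Mean-level totals of observed and potential AGB in the disturbed
#' zone; the shaded gap between the two curves is the deficit.
#'
#' @param object A `potential_run` (from [run_ensemble()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.potential_run <- function(object, ...) {
  dt <- object$deficit_table
  dt <- dt[dt$level == "mean", ]
  long <- tidyr::pivot_longer(dt[c("year", "agb_obs_pg", "agb_pot_pg")],
                              -"year", names_to = "series",
                              values_to = "pg")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$pg,
                                     colour = .data$series)) +
    ggplot2::geom_ribbon(
      data = dt,
      ggplot2::aes(x = .data$year, ymin = .data$agb_obs_pg,
                   ymax = .data$agb_pot_pg),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(agb_obs_pg = "black", agb_pot_pg = "steelblue"),
      labels = c(agb_obs_pg = "Observed", agb_pot_pg = "Potential"),
      name = NULL) +
    ggplot2::labs(x = "Year", y = "AGB total (Pg C)") +
    ggplot2::theme_minimal()
}

#' Map per-pixel temporal correlations with a significance overlay
#'
#' Tile map of the per-pixel Pearson correlation; significant pixels
#' (p < 0.05, uncorrected) are overdrawn with points, the tile-map
#' analogue of hatching.
#'
#' @param cor_map Output of [pixelwise_temporal_correlation()].
#' @return A ggplot object.
#' @export
plot_correlation_map <- function(cor_map) {
  stopifnot(all(c("lat", "lon", "r", "significant") %in% names(cor_map)))
  ggplot2::ggplot(cor_map, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r)) +
    ggplot2::geom_point(data = cor_map[cor_map$significant, ],
                        shape = 4, size = 0.8, colour = "black") +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "darkblue", midpoint = 0,
                                  limits = c(-1, 1), na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "r") +
    ggplot2::theme_minimal()
}
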
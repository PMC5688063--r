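#' Define a regular latitude-longitude grid
#'
#' A grid is the geometry every raster tibble in the package refers to:
#' a regular lat/lon lattice at a fixed resolution, with coordinates at
#' cell centers and half-open cells `[edge, edge + resolution)`. The
#' canonical ordering is south-to-north, then west-to-east.
#'
#' @param lat_min,lat_max,lon_min,lon_max Domain edges in degrees.
#' @param resolution Cell size in degrees (default 0.25).
#' @return A `grid_spec` object (a list with the edges, resolution and
#'   cell counts `n_lat`, `n_lon`).
#' @examples
#' grid_spec(-15, -5, -70, -60)
#' @export
grid_spec <- function(lat_min, lat_max, lon_min, lon_max, resolution = 0.25) {
  stopifnot(lat_max > lat_min, lon_max > lon_min, resolution > 0)
  if (lat_min < -90 || lat_max > 90) {
    stop("latitude edges must lie in [-90, 90]", call. = FALSE)
  }
  n_lat <- (lat_max - lat_min) / resolution
  n_lon <- (lon_max - lon_min) / resolution
  if (abs(n_lat - round(n_lat)) > 1e-8 || abs(n_lon - round(n_lon)) > 1e-8) {
    stop("grid extent is not an integer multiple of the resolution",
         call. = FALSE)
  }
  structure(
    list(lat_min = lat_min, lat_max = lat_max,
         lon_min = lon_min, lon_max = lon_max,
         resolution = resolution,
         n_lat = as.integer(round(n_lat)), n_lon = as.integer(round(n_lon))),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g deg, %d x %d cells, lat [%g, %g], lon [%g, %g]\n",
              x$resolution, x$n_lat, x$n_lon,
              x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cell (`pixel`, `lat`, `lon`) in
#'   canonical order: south-to-north, west-to-east within each row.
#' @export
grid_pixels <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  lats <- grid$lat_min + (seq_len(grid$n_lat) - 0.5) * grid$resolution
  lons <- grid$lon_min + (seq_len(grid$n_lon) - 0.5) * grid$resolution
  tibble::tibble(
    pixel = seq_len(grid$n_lat * grid$n_lon),
    lat = rep(lats, each = grid$n_lon),
    lon = rep(lons, times = grid$n_lat)
  )
}

# Mean Earth radius, metres. Used for all geodesic cell areas.
EARTH_RADIUS_M <- 6371000

#' Geodesic area of a grid cell, in hectares
#'
#' Area of a latitude band segment on the sphere:
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`, with R the mean
#' Earth radius (6,371,000 m). Vectorised over `lat`.
#'
#' @param lat Cell-center latitude(s), degrees.
#' @param resolution Cell size in degrees (default 0.25).
#' @return Cell area(s) in hectares.
#' @examples
#' cell_area_ha(0) # ~77,277 ha for a 0.25 deg cell on the equator
#' @export
cell_area_ha <- function(lat, resolution = 0.25) {
  if (any(abs(lat) > 90, na.rm = TRUE)) {
    stop("cell-center latitude outside [-90, 90]", call. = FALSE)
  }
  half <- resolution / 2
  phi_top <- pmin(lat + half, 90) * pi / 180
  phi_bot <- pmax(lat - half, -90) * pi / 180
  dlambda <- resolution * pi / 180
  EARTH_RADIUS_M^2 * dlambda * (sin(phi_top) - sin(phi_bot)) / 1e4
}

#' Area-weighted total of a biomass density field, in Pg C
#'
#' Summarise helper: converts per-hectare carbon densities to a regional
#' total, weighting each cell by its geodesic area. Missing values
#' contribute zero (they are excluded, never treated as 0 density).
#' `1 Mg C ha^-1 * ha = 1 Mg C`; `1 Pg = 1e9 Mg`.
#'
#' @param value Densities in Mg C ha^-1.
#' @param lat Cell-center latitudes (same length as `value`).
#' @param resolution Grid resolution in degrees.
#' @return Total in Pg C (scalar).
#' @export
total_pg <- function(value, lat, resolution = 0.25) {
  keep <- !is.na(value)
  sum(value[keep] * cell_area_ha(lat[keep], resolution)) * 1e-9
}

#' Aggregate a raster tibble to a basin total
#'
#' @param field A raster tibble with `lat`, `lon` and a value column, in
#'   Mg C ha^-1 (checked against the tibble's `units` attribute when one
#'   is present).
#' @param mask Optional logical vector (recycled length-1 or per-row) or
#'   the name of a logical column of `field`; only `TRUE` rows count.
#' @param value Name of the value column (default `"value"`).
#' @param resolution Grid resolution; defaults to the `grid` attribute's
#'   resolution, else 0.25.
#' @return Total in Pg C.
#' @export
aggregate_total <- function(field, mask = NULL, value = "value",
                            resolution = NULL) {
  stopifnot(is.data.frame(field), all(c("lat", value) %in% names(field)))
  units <- attr(field, "units")
  if (!is.null(units) && !identical(units, "Mg C ha-1")) {
    stop("aggregate_total() expects densities in 'Mg C ha-1', got units '",
         units, "'", call. = FALSE)
  }
  if (is.null(resolution)) {
    g <- attr(field, "grid")
    resolution <- if (inherits(g, "grid_spec")) g$resolution else 0.25
  }
  if (is.character(mask) && length(mask) == 1) {
    mask <- field[[mask]]
    if (is.null(mask)) stop("mask column not found", call. = FALSE)
  }
  if (is.null(mask)) mask <- TRUE
  keep <- rep_len(as.logical(mask), nrow(field)) & !is.na(field[[value]])
  total_pg(field[[value]][keep], field$lat[keep], resolution)
}

#' Attach grid and unit metadata to a raster tibble
#'
#' @param df Tibble with `lat`, `lon` and value column(s).
#' @param grid A [grid_spec()].
#' @param units Unit string carried as metadata (e.g. `"Mg C ha-1"`).
#' @return `df` with `grid` and `units` attributes, rows in canonical
#'   south-to-north / west-to-east order.
#' @export
as_raster <- function(df, grid, units = "Mg C ha-1") {
  stopifnot(is.data.frame(df), all(c("lat", "lon") %in% names(df)))
  df <- dplyr::arrange(df, .data$lat, .data$lon)
  attr(df, "grid") <- grid
  attr(df, "units") <- units
  df
}

#' Write a raster tibble to a plain-text file
#'
#' The on-disk format is a CSV in long form (`lat`, `lon`, value columns)
#' preceded by `#`-prefixed metadata lines recording the grid extent,
#' resolution and units. Plain text keeps the files diffable and
#' dependency-free; values are written with shortest round-trip precision
#' so a write/read cycle is bit-exact.
#'
#' @param field Raster tibble (see [as_raster()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(field, path) {
  grid <- attr(field, "grid")
  if (!inherits(grid, "grid_spec")) {
    stop("field has no grid_spec attribute; see as_raster()", call. = FALSE)
  }
  units <- attr(field, "units")
  header <- c(
    "# potbiomass raster v1",
    sprintf("# units: %s", if (is.null(units)) "unknown" else units),
    sprintf("# resolution: %.*g", 15, grid$resolution),
    sprintf("# lat_min: %.*g", 15, grid$lat_min),
    sprintf("# lat_max: %.*g", 15, grid$lat_max),
    sprintf("# lon_min: %.*g", 15, grid$lon_min),
    sprintf("# lon_max: %.*g", 15, grid$lon_max)
  )
  writeLines(header, path)
  out <- dplyr::arrange(field, .data$lat, .data$lon)
  # 17 significant digits round-trip IEEE doubles exactly
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))))
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a raster tibble written by [write_raster()]
#'
#' Latitude/longitude ordering in the file is normalised to the canonical
#' south-to-north, west-to-east order on read.
#'
#' @param path Input path.
#' @param grid Optional expected [grid_spec()]; a mismatch with the grid
#'   recorded in the file is a format error.
#' @return Raster tibble with `grid` and `units` attributes.
#' @export
read_raster <- function(path, grid = NULL) {
  head_lines <- readLines(path, n = 8)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), meta_lines, value = TRUE)
    if (length(ln) != 1) {
      stop("raster file is missing metadata field '", key, "'", call. = FALSE)
    }
    sub(paste0("^# ", key, ": "), "", ln)
  }
  units <- get_meta("units")
  file_grid <- grid_spec(
    lat_min = as.numeric(get_meta("lat_min")),
    lat_max = as.numeric(get_meta("lat_max")),
    lon_min = as.numeric(get_meta("lon_min")),
    lon_max = as.numeric(get_meta("lon_max")),
    resolution = as.numeric(get_meta("resolution"))
  )
  if (!is.null(grid) && !identical(unclass(grid), unclass(file_grid))) {
    stop("grid in file does not match the expected grid_spec", call. = FALSE)
  }
  # base read.csv parses doubles through strtod, which is correctly
  # rounded; this keeps the write/read cycle bit-exact
  df <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  if (!all(c("lat", "lon") %in% names(df))) {
    stop("raster file lacks lat/lon coordinate columns", call. = FALSE)
  }
  as_raster(df, file_grid, units = if (units == "unknown") NULL else units)
}

#' Read or write a 1-D index series as CSV
#'
#' Series files are plain CSVs with a label column (`year` or `label`)
#' and a `value` column.
#'
#' @param series Tibble with a label column and `value`.
#' @param path File path.
#' @return `read_series()` returns a tibble; `write_series()` returns
#'   `path` invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(is.data.frame(series))
  readr::write_csv(series, path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
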
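test_that("cell areas follow the spherical closed form", {
  # frozen value computed independently: R^2 * dlambda * (sin p2 - sin p1)
  # with R = 6,371,000 m for a 0.25 deg cell centred on the equator
  expect_equal(cell_area_ha(0), 77276.88689498477, tolerance = 1e-12)
  # monotone decrease away from the equator, down to the polar cell
  lats <- c(0, 10, 30, 60, 85, 89.875)
  expect_true(all(diff(cell_area_ha(lats)) < 0))
  expect_lt(cell_area_ha(89.875), cell_area_ha(0))
  expect_true(all(cell_area_ha(c(-89.875, 89.875)) > 0))
  expect_error(cell_area_ha(91), "latitude")
})

test_that("cell areas close the sphere", {
  res <- 2.5
  lats <- seq(-90 + res / 2, 90 - res / 2, by = res)
  total <- sum(cell_area_ha(lats, res)) * (360 / res)
  sphere <- 4 * pi * 6371000^2 / 1e4
  expect_equal(total, sphere, tolerance = 1e-6)
})

test_that("aggregation converts density to Pg C with area weights", {
  g <- grid_spec(-0.25, 0.25, 0, 0.5)
  px <- grid_pixels(g)
  field <- as_raster(dplyr::mutate(px, value = 0), g)
  expect_identical(aggregate_total(field), 0)
  # one known cell: 100 Mg C/ha over an equatorial 0.25 deg cell
  one <- as_raster(tibble::tibble(lat = 0.125, lon = 0.25, value = 100), g)
  expect_equal(aggregate_total(one), 100 * cell_area_ha(0.125) * 1e-9,
               tolerance = 1e-12)
  # missing values are excluded, not zero (same total either way here,
  # but the NA row must not poison the sum)
  two <- as_raster(tibble::tibble(lat = c(0.125, -0.125), lon = 0.25,
                                  value = c(100, NA)), g)
  expect_equal(aggregate_total(two), aggregate_total(one))
})

test_that("aggregation is additive over disjoint masks and linear", {
  g <- grid_spec(-5, 0, 10, 15)
  px <- grid_pixels(g)
  set.seed(42)
  f <- as_raster(dplyr::mutate(px, value = runif(nrow(px), 0, 200)), g)
  m1 <- px$lon < 12.5
  m2 <- !m1
  expect_equal(aggregate_total(f, m1) + aggregate_total(f, m2),
               aggregate_total(f), tolerance = 1e-12)
  f2 <- f
  f2$value <- 3 * f$value
  expect_equal(aggregate_total(f2, m1), 3 * aggregate_total(f, m1),
               tolerance = 1e-12)
})

test_that("unit metadata is enforced at aggregation", {
  g <- grid_spec(-5, 0, 10, 15)
  f <- as_raster(dplyr::mutate(grid_pixels(g), value = 1), g, units = "mm")
  expect_error(aggregate_total(f), "units")
})

test_that("raster files round-trip bit-exactly and normalise orientation", {
  g <- grid_spec(-5, 0, 10, 15)
  set.seed(7)
  f <- as_raster(dplyr::mutate(grid_pixels(g),
                               value = rnorm(400, 100, 30)), g)
  f$value[c(3, 50)] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster(f, path)
  back <- read_raster(path)
  expect_identical(back$value, f$value)
  expect_identical(back$lat, f$lat)
  expect_identical(attr(back, "units"), "Mg C ha-1")
  expect_identical(unclass(attr(back, "grid")), unclass(g))
  # scrambled row order on disk comes back canonical (south-to-north)
  scrambled <- f[rev(seq_len(nrow(f))), ]
  attr(scrambled, "grid") <- g
  attr(scrambled, "units") <- "Mg C ha-1"
  write_raster(scrambled, path)
  expect_identical(read_raster(path)$value, f$value)
})

test_that("malformed raster files are format errors", {
  g <- grid_spec(-5, 0, 10, 15)
  f <- as_raster(dplyr::mutate(grid_pixels(g), value = 1), g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster(f, path)
  expect_error(read_raster(path, grid = grid_spec(-5, 0, 10, 20)),
               "does not match")
  # strip the coordinate column
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  writeLines(c("# potbiomass raster v1", "# units: Mg C ha-1",
               "# resolution: 0.25", "# lat_min: -5", "# lat_max: 0",
               "# lon_min: 10", "# lon_max: 15"), path)
  readr::write_csv(df[c("value")], path, append = TRUE, col_names = TRUE)
  expect_error(read_raster(path), "coordinate")
})

test_that("grid definition validates its invariants", {
  expect_error(grid_spec(-5, 0, 10, 15.1), "integer multiple")
  expect_error(grid_spec(-95, 0, 10, 15), "latitude")
  g <- grid_spec(-5, 0, 10, 15)
  expect_identical(g$n_lat, 20L)
  expect_identical(g$n_lon, 20L)
  px <- grid_pixels(g)
  expect_identical(nrow(px), 400L)
  # cell centers, half-open cells: first center half a cell from edge
  expect_equal(min(px$lat), -5 + 0.125)
  expect_equal(max(px$lon), 15 - 0.125)
})
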
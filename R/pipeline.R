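#' Assemble the training/prediction table for one year and level
#'
#' Joins one year's observed-AGB layer at one quantile level onto the
#' static feature table (monthly climatology layers, latitude, water
#' flag).
#'
#' @param world A `synthetic_world` or any list with `features`,
#'   `feature_names`, `pixels` and `agb_obs` of the same shape.
#' @param year Study year.
#' @param level Quantile level: `"q05"`, `"mean"` or `"q95"`.
#' @return Tibble with `pixel`, `lat`, `lon`, `water`, the feature
#'   columns, mask columns and `agb`.
#' @export
training_table <- function(world, year, level = "mean") {
  obs <- world$agb_obs
  layer <- obs[obs$year == year & obs$level == level, c("pixel", "agb")]
  if (nrow(layer) == 0) {
    stop("no AGB layer for year ", year, " level '", level, "'",
         call. = FALSE)
  }
  world$features |>
    dplyr::left_join(world$pixels[c("pixel", "basin", "ifl")], by = "pixel") |>
    dplyr::left_join(layer, by = "pixel")
}

#' Reconstruct the potential-AGB map for one year
#'
#' Trains a model-tree ensemble on that year's observed AGB over
#' intact-forest pixels only (features: monthly climatology, latitude,
#' open-water flag) and predicts the climate-driven potential AGB on the
#' disturbed part of the basin. Intact pixels are at potential by
#' definition, so their potential is reported as their observed value.
#'
#' @inheritParams training_table
#' @param n_trees,max_depth,min_leaf_rows,mtry Forest hyperparameters
#'   (see [fit_forest()]).
#' @param seed Master seed for the forest fit.
#' @param min_train_rows Minimum usable intact training rows; fewer is a
#'   configuration error (default `2 * min_leaf_rows`, i.e. enough rows
#'   for at least one split with determined leaf regressions).
#' @return A list: `forest` (the fitted `model_tree_forest`) and `map`,
#'   a raster tibble with `pixel`, `lat`, `lon`, `obs`, `pot`, `deficit`
#'   (`pot` missing outside the basin).
#' @export
run_year <- function(world, year, level = "mean", n_trees = 100,
                     max_depth = 12, min_leaf_rows = NULL, mtry = NULL,
                     seed = 1, min_train_rows = NULL) {
  tab <- training_table(world, year, level)
  fnames <- world$feature_names
  train <- tab[tab$ifl & !is.na(tab$agb), ]
  p <- length(fnames)
  if (is.null(min_leaf_rows)) min_leaf_rows <- 2L * (p + 1L)
  if (is.null(min_train_rows)) min_train_rows <- 2L * min_leaf_rows
  if (nrow(train) == 0) {
    stop("year ", year, ": all intact-forest AGB values are missing",
         call. = FALSE)
  }
  if (nrow(train) < min_train_rows) {
    stop("year ", year, ": only ", nrow(train),
         " intact training rows; need at least ", min_train_rows,
         call. = FALSE)
  }
  forest <- fit_forest(train, target = "agb", features = fnames,
                       categorical = "water", n_trees = n_trees,
                       max_depth = max_depth, min_leaf_rows = min_leaf_rows,
                       mtry = mtry, seed = seed)
  predict_zone <- tab$basin & !tab$ifl
  pot <- rep(NA_real_, nrow(tab))
  pot[predict_zone] <- predict(forest, tab[predict_zone, ])
  pot[tab$ifl] <- tab$agb[tab$ifl]
  map <- tibble::tibble(
    pixel = tab$pixel, lat = tab$lat, lon = tab$lon,
    water = tab$water, ifl = tab$ifl, basin = tab$basin,
    obs = ifelse(tab$basin, tab$agb, NA_real_),
    pot = pot
  )
  map$deficit <- map$pot - map$obs
  map <- as_raster(map, world$grid, units = "Mg C ha-1")
  list(forest = forest, map = map, year = year, level = level)
}

#' Run the reconstruction for all years and quantile levels
#'
#' Executes [run_year()] independently for every (year, level)
#' combination - the percentile levels propagate the observation
#' uncertainty through the whole pipeline - with the same master seed
#' across years and levels, so ensemble differences reflect input
#' differences rather than sampling noise. Basin totals are restricted
#' to the disturbed (basin minus intact) zone and weighted by geodesic
#' cell area.
#'
#' @inheritParams run_year
#' @param years Years to run (default all in `world`).
#' @param levels Quantile levels (default `c("q05", "mean", "q95")`).
#' @param keep_forests Keep each fitted forest in the result (default
#'   `FALSE`: only per-tree summaries are kept, the maps always are).
#' @return A list of class `potential_run`: `maps` (tibble with `pixel`,
#'   `lat`, `lon`, `year`, `level`, `obs`, `pot`, `deficit`),
#'   `deficit_table` (class `deficit_table`: `year`, `level`,
#'   `agb_obs_pg`, `agb_pot_pg`, `agb_def_pg`, `deficit_fraction`),
#'   `forests` (when kept), and the run settings.
#' @export
run_ensemble <- function(world, years = NULL, levels = c("q05", "mean", "q95"),
                         n_trees = 100, max_depth = 12, min_leaf_rows = NULL,
                         mtry = NULL, seed = 1, keep_forests = FALSE) {
  if (is.null(years)) years <- world$config$years
  have <- unique(world$agb_obs$level)
  missing_lev <- setdiff(levels, have)
  if (length(missing_lev) > 0) {
    stop("AGB level(s) absent from the input series: ",
         paste(missing_lev, collapse = ", "), call. = FALSE)
  }
  res <- world$grid$resolution
  combos <- tidyr::expand_grid(level = levels, year = years)
  runs <- purrr::pmap(combos, function(level, year) {
    run_year(world, year, level, n_trees = n_trees, max_depth = max_depth,
             min_leaf_rows = min_leaf_rows, mtry = mtry, seed = seed)
  })
  maps <- purrr::map_dfr(runs, function(r) {
    dplyr::mutate(r$map, year = r$year, level = r$level)
  })
  disturbed <- maps$basin & !maps$ifl
  deficit_table <- maps[disturbed, ] |>
    dplyr::group_by(.data$year, .data$level) |>
    dplyr::summarise(
      agb_obs_pg = total_pg(.data$obs, .data$lat, res),
      agb_pot_pg = total_pg(.data$pot, .data$lat, res),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      agb_def_pg = .data$agb_pot_pg - .data$agb_obs_pg,
      deficit_fraction = ifelse(.data$agb_pot_pg > 0,
                                .data$agb_def_pg / .data$agb_pot_pg,
                                NA_real_)
    )
  class(deficit_table) <- c("deficit_table", class(deficit_table))
  out <- list(
    maps = maps,
    deficit_table = deficit_table,
    tree_summaries = purrr::map_dfr(runs, function(r) {
      dplyr::mutate(glance(r$forest), year = r$year, level = r$level)
    }),
    years = years, levels = levels, seed = seed,
    params = list(n_trees = n_trees, max_depth = max_depth,
                  min_leaf_rows = min_leaf_rows, mtry = mtry),
    grid = world$grid
  )
  if (keep_forests) out$forests <- runs
  structure(out, class = "potential_run")
}

#' @export
print.potential_run <- function(x, ...) {
  cat(sprintf("<potential_run> %d year(s) x %d level(s), %d trees, seed %d\n",
              length(x$years), length(x$levels), x$params$n_trees, x$seed))
  print(x$deficit_table, n = 6)
  invisible(x)
}

#' Biomass-deficit map
#'
#' Pixel-wise `potential - observed`. Missing where either input is
#' missing; deliberately not clipped at zero - negative values mark
#' pixels where regrowth carried observed stocks above the modelled
#' potential (partial recovery).
#'
#' @param pot,obs Raster tibbles with `lat`, `lon` and a value column.
#' @param value Value column name in both inputs (default `"value"`).
#' @return Raster tibble `lat`, `lon`, `value` (Mg C ha^-1).
#' @export
deficit_map <- function(pot, obs, value = "value") {
  stopifnot(all(c("lat", "lon", value) %in% names(pot)),
            all(c("lat", "lon", value) %in% names(obs)))
  m <- dplyr::inner_join(pot[c("lat", "lon", value)],
                         obs[c("lat", "lon", value)],
                         by = c("lat", "lon"), suffix = c("_pot", "_obs"))
  out <- tibble::tibble(lat = m$lat, lon = m$lon,
                        value = m[[paste0(value, "_pot")]] -
                          m[[paste0(value, "_obs")]])
  g <- attr(pot, "grid")
  if (inherits(g, "grid_spec")) out <- as_raster(out, g, units = "Mg C ha-1")
  out
}

#' Scalar deficit arithmetic on basin totals
#'
#' From first- and last-year basin totals, per quantile level: the
#' observed loss `obs(first) - obs(last)`, the change in potential, the
#' deficits `pot - obs` in the first and last year, the deficit change,
#' the mean deficit growth rate over the period, and the pre-period rate
#' `deficit(first) / (first - start_year)` under the assumption that
#' large-scale clearing began in `start_year`.
#'
#' @param table A deficit table: tibble with `year`, `level`,
#'   `agb_obs_pg`, `agb_pot_pg` (Pg C). Only the first and last year of
#'   each level are used.
#' @param start_year Assumed onset year of large-scale clearing
#'   (default 1960).
#' @return Tibble with one row per level: `level`, `year_first`,
#'   `year_last`, `obs_loss_pg`, `pot_change_pg`, `deficit_first_pg`,
#'   `deficit_last_pg`, `deficit_change_pg`, `mean_rate_pg_yr`,
#'   `pre_period_rate_pg_yr`.
#' @examples
#' totals <- tibble::tibble(
#'   year = c(1993, 2012), level = "mean",
#'   agb_obs_pg = c(26.3, 24.1), agb_pot_pg = c(32.1, 31.4)
#' )
#' deficit_arithmetic(totals)
#' @export
deficit_arithmetic <- function(table, start_year = 1960) {
  stopifnot(is.data.frame(table),
            all(c("year", "level", "agb_obs_pg", "agb_pot_pg") %in%
                  names(table)))
  if (any(!is.finite(table$agb_obs_pg)) || any(!is.finite(table$agb_pot_pg))) {
    stop("totals must be finite", call. = FALSE)
  }
  table |>
    dplyr::group_by(.data$level) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::summarise(
      year_first = dplyr::first(.data$year),
      year_last = dplyr::last(.data$year),
      obs_loss_pg = dplyr::first(.data$agb_obs_pg) -
        dplyr::last(.data$agb_obs_pg),
      pot_change_pg = dplyr::first(.data$agb_pot_pg) -
        dplyr::last(.data$agb_pot_pg),
      deficit_first_pg = dplyr::first(.data$agb_pot_pg) -
        dplyr::first(.data$agb_obs_pg),
      deficit_last_pg = dplyr::last(.data$agb_pot_pg) -
        dplyr::last(.data$agb_obs_pg),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      deficit_change_pg = .data$deficit_last_pg - .data$deficit_first_pg,
      period_years = .data$year_last - .data$year_first,
      mean_rate_pg_yr = {
        if (any(.data$period_years == 0)) {
          stop("zero-length period: first and last year coincide",
               call. = FALSE)
        }
        .data$deficit_change_pg / .data$period_years
      },
      pre_period_rate_pg_yr = .data$deficit_first_pg /
        (.data$year_first - start_year)
    ) |>
    dplyr::select(-"period_years")
}
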
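#' Random train/holdout split of the intact-forest mask
#'
#' Partitions the intact-forest pixels at random into a training set and
#' a holdout set; deterministic given the seed.
#'
#' @param pixels Tibble with `pixel` and logical `ifl` columns (e.g. a
#'   `synthetic_world`'s `pixels`).
#' @param fraction Fraction of intact pixels assigned to training
#'   (default 0.5).
#' @param seed Integer seed.
#' @param min_train_rows Minimum intact pixels required on each side of
#'   the split; fewer is a configuration error.
#' @return `pixels` with a logical `holdout` column (`NA` outside the
#'   intact mask): `ifl & !holdout` trains, `ifl & holdout` validates.
#' @export
split_ifl <- function(pixels, fraction = 0.5, seed = 1,
                      min_train_rows = 10) {
  stopifnot(is.data.frame(pixels), all(c("pixel", "ifl") %in% names(pixels)),
            fraction > 0, fraction < 1)
  ifl_ids <- pixels$pixel[pixels$ifl]
  n_ifl <- length(ifl_ids)
  n_train <- round(fraction * n_ifl)
  if (n_train < min_train_rows || (n_ifl - n_train) < min_train_rows) {
    stop("too few intact pixels (", n_ifl, ") to split ", fraction, "/",
         1 - fraction, " with at least ", min_train_rows, " per side",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  train_ids <- sort(sample(ifl_ids, n_train))
  pixels$holdout <- ifelse(pixels$ifl, !(pixels$pixel %in% train_ids), NA)
  pixels
}

#' Out-of-sample validation on held-out intact-forest pixels
#'
#' Trains the reconstruction on a random half (by default) of the intact
#' pixels and predicts the other half, year by year. Two bias metrics
#' are reported, following the distinction between the basin-integrated
#' and the typical local error: `integrated_bias_pct` is the bias of the
#' area-weighted holdout total, `(sum pred - sum obs) / sum obs * 100`;
#' `local_mean_relative_bias_pct` is the unweighted mean over holdout
#' pixels of the per-pixel relative bias, restricted to pixels whose
#' observed density exceeds `floor_mg_ha` (near-zero denominators would
#' otherwise dominate the mean).
#'
#' @inheritParams run_year
#' @param fraction Training fraction of the intact mask (default 0.5).
#' @param split_seed Seed of the random split (default `seed`).
#' @param years Years to validate (default all).
#' @param floor_mg_ha Observed-density floor for the local relative bias
#'   (default 10 Mg C ha^-1).
#' @return A `validation_report`: list with `per_year` (tibble of both
#'   bias metrics per year), `pooled` (one-row tibble over all years),
#'   `residuals` (tibble `pixel`, `lat`, `year`, `obs`, `pred`,
#'   `residual`), and the split settings. The metrics are exactly
#'   recomputable from `residuals`.
#' @export
holdout_validate <- function(world, fraction = 0.5, level = "mean",
                             n_trees = 100, max_depth = 12,
                             min_leaf_rows = NULL, mtry = NULL, seed = 1,
                             split_seed = seed, years = NULL,
                             floor_mg_ha = 10) {
  if (is.null(years)) years <- world$config$years
  fnames <- world$feature_names
  p <- length(fnames)
  if (is.null(min_leaf_rows)) min_leaf_rows <- 2L * (p + 1L)
  px <- split_ifl(world$pixels, fraction = fraction, seed = split_seed,
                  min_train_rows = 2L * min_leaf_rows)
  res <- world$grid$resolution
  residuals <- purrr::map_dfr(years, function(y) {
    tab <- training_table(world, y, level)
    tab$holdout <- px$holdout[match(tab$pixel, px$pixel)]
    train <- tab[tab$ifl & !tab$holdout %in% TRUE & !is.na(tab$agb), ]
    hold <- tab[tab$ifl & tab$holdout %in% TRUE & !is.na(tab$agb), ]
    forest <- fit_forest(train, target = "agb", features = fnames,
                         categorical = "water", n_trees = n_trees,
                         max_depth = max_depth, min_leaf_rows = min_leaf_rows,
                         mtry = mtry, seed = seed)
    tibble::tibble(
      pixel = hold$pixel, lat = hold$lat, year = y,
      obs = hold$agb, pred = predict(forest, hold)
    )
  })
  residuals$residual <- residuals$pred - residuals$obs
  bias_metrics <- function(df) {
    tot_obs <- total_pg(df$obs, df$lat, res)
    tot_pred <- total_pg(df$pred, df$lat, res)
    loc <- df[df$obs > floor_mg_ha, ]
    tibble::tibble(
      n_pixels = nrow(df),
      integrated_bias_pct = 100 * (tot_pred - tot_obs) / tot_obs,
      local_mean_relative_bias_pct =
        100 * mean((loc$pred - loc$obs) / loc$obs)
    )
  }
  per_year <- residuals |>
    dplyr::group_by(.data$year) |>
    dplyr::group_modify(~ bias_metrics(.x)) |>
    dplyr::ungroup()
  structure(
    list(per_year = per_year, pooled = bias_metrics(residuals),
         residuals = residuals,
         split = list(fraction = fraction, seed = split_seed,
                      floor_mg_ha = floor_mg_ha, level = level,
                      forest_seed = seed, n_trees = n_trees)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d years, %d holdout pixels; pooled bias %.3f%%, local %.3f%%\n",
    nrow(x$per_year), x$pooled$n_pixels, x$pooled$integrated_bias_pct,
    x$pooled$local_mean_relative_bias_pct))
  invisible(x)
}

#' Glance at a validation report
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return One-row tibble of the pooled metrics and split settings.
#' @export
glance.validation_report <- function(x, ...) {
  dplyr::mutate(x$pooled,
                fraction = x$split$fraction, split_seed = x$split$seed,
                n_years = nrow(x$per_year))
}

#' Compare deficit dynamics with independent land-use series
#'
#' Two correlations: annual deficit increments against a clearing-rate
#' series (clearing adds deficit, so the association should be strongly
#' positive when clearing drives the dynamics), and the deficit total
#' against the basin-total primary-land fraction (erosion of primary
#' land should track a growing deficit, a negative association).
#'
#' @param deficit_series Tibble `year`, `value`: deficit totals, Pg C.
#' @param deforestation_rate Tibble `year`, `value`: clearing rate.
#' @param primary_fraction_total Optional tibble `year`, `value`:
#'   basin-total primary fraction.
#' @return Tibble with one row per comparison: `comparison`, `r`, `n`,
#'   `p`.
#' @export
compare_deficit_to_lulcc <- function(deficit_series, deforestation_rate,
                                     primary_fraction_total = NULL) {
  out <- dplyr::mutate(
    correlate(annual_delta(deficit_series), deforestation_rate),
    comparison = "deficit_increment_vs_clearing_rate", .before = 1)
  if (!is.null(primary_fraction_total)) {
    out <- dplyr::bind_rows(
      out,
      dplyr::mutate(correlate(deficit_series, primary_fraction_total),
                    comparison = "deficit_total_vs_primary_fraction",
                    .before = 1))
  }
  out
}
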
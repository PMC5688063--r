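#' Configuration of a synthetic gridded world
#'
#' Bundles the knobs of the synthetic data generator: grid geometry,
#' study years, climate variables, the intact-forest fraction, the
#' ENSO coupling of the potential-biomass anomaly, and the disturbance,
#' regrowth and observation-noise settings. Defaults emulate the
#' statistical structure of the Amazon-basin study conditions: a 0.25
#' degree grid, 1993-2012, intact landscapes covering ~55% of the basin,
#' a rising biomass deficit in the disturbed zone, and a symmetric
#' 5th/95th-percentile observation spread.
#'
#' @param grid A [grid_spec()]; default a 40 x 40 cell 0.25 degree domain.
#' @param years Study years (default 1993:2012).
#' @param seed Integer seed; all of the generator's randomness flows
#'   from it.
#' @param climate_vars Climate variable names, each with 12 monthly
#'   layers (default precipitation `pre`, mean temperature `tmp`,
#'   diurnal temperature range `dtr`).
#' @param ifl_fraction Target fraction of basin pixels that are intact
#'   (default 0.55).
#' @param water_fraction Fraction of basin pixels flagged as large-scale
#'   open water (default 0.02); their observed AGB is constant in time.
#' @param enso_coupling Amplitude of the ENSO-driven potential-AGB
#'   anomaly, Mg C ha^-1 per winter-composite index unit (default -2:
#'   El Nino reduces the potential).
#' @param disturbance_intensity Per-year clearing probability scale in
#'   the disturbed zone (default 0.02).
#' @param regrowth_rate Fractional annual recovery of a cleared pixel's
#'   biomass toward its potential (default 0.03).
#' @param obs_spread Relative half-width between the 5th and 95th
#'   percentile observation maps (default 0.08).
#' @param obs_noise Additive observation noise sd on the mean map,
#'   Mg C ha^-1 (default 2).
#' @param interannual_sd Sd of the non-ENSO interannual potential
#'   anomaly, Mg C ha^-1 (default 1).
#' @param clearing_start_year First year of the clearing process; the
#'   generator burns in the disturbance history from this year to the
#'   first study year (default 1960).
#' @return A `world_config` object.
#' @export
world_config <- function(grid = grid_spec(-15, -5, -70, -60, 0.25),
                         years = 1993:2012,
                         seed = 1,
                         climate_vars = c("pre", "tmp", "dtr"),
                         ifl_fraction = 0.55,
                         water_fraction = 0.02,
                         enso_coupling = -2,
                         disturbance_intensity = 0.02,
                         regrowth_rate = 0.03,
                         obs_spread = 0.08,
                         obs_noise = 2,
                         interannual_sd = 1,
                         clearing_start_year = 1960) {
  stopifnot(inherits(grid, "grid_spec"),
            ifl_fraction > 0, ifl_fraction < 1,
            water_fraction >= 0, water_fraction < 1,
            regrowth_rate >= 0, regrowth_rate < 1,
            obs_spread >= 0, obs_noise >= 0, interannual_sd >= 0,
            disturbance_intensity >= 0,
            length(years) >= 2, all(diff(years) == 1),
            clearing_start_year <= min(years))
  structure(
    list(grid = grid, years = as.integer(years), seed = as.integer(seed),
         climate_vars = climate_vars, ifl_fraction = ifl_fraction,
         water_fraction = water_fraction, enso_coupling = enso_coupling,
         disturbance_intensity = disturbance_intensity,
         regrowth_rate = regrowth_rate, obs_spread = obs_spread,
         obs_noise = obs_noise, interannual_sd = interannual_sd,
         clearing_start_year = as.integer(clearing_start_year)),
    class = "world_config"
  )
}

# Smooth, spatially correlated random surface on the unit square:
# a sum of k random low-frequency cosine waves, standardised. Climate
# surfaces use enough wave components that both the intact and the
# disturbed zone sample the full climate envelope (real sub-degree
# climatologies carry comparable fine-scale orographic structure);
# without that coverage a space-for-time model has nothing to learn
# the dry tail from.
smooth_surface <- function(u, v, k = 8, freq_max = 2) {
  f <- numeric(length(u))
  for (i in seq_len(k)) {
    amp <- stats::rnorm(1)
    fu <- stats::runif(1, -freq_max, freq_max)
    fv <- stats::runif(1, -freq_max, freq_max)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + amp * cos(2 * pi * (fu * u + fv * v) + ph)
  }
  as.numeric(scale(f))
}

# The true potential-biomass surface: linear in the annual-mean climate
# layers plus a saturating precipitation term and a temperature x
# moisture interaction, so a model-tree ensemble can approximate it well
# but one global linear model cannot.
true_potential_fun <- function(coef) {
  force(coef)
  function(pre_ann, tmp_ann, dtr_ann, lat) {
    coef$b0 +
      coef$b_sat * tanh((pre_ann - coef$p0) / coef$p_scale) +
      coef$b_tmp * (tmp_ann - coef$t0) +
      coef$b_dtr * (dtr_ann - coef$d0) +
      coef$b_int * (tmp_ann - coef$t0) * tanh((pre_ann - coef$p0) / coef$p_scale) +
      coef$b_lat * lat
  }
}

default_truth_coef <- function() {
  list(b0 = 120, b_sat = 60, p0 = 160, p_scale = 60,
       b_tmp = -4, b_dtr = -3, b_int = 1.2, t0 = 26, d0 = 10, b_lat = 1.5)
}

#' Generate a complete synthetic input bundle with known ground truth
#'
#' Builds everything the reconstruction pipeline consumes: a static
#' monthly climatology (smooth spatially correlated surfaces with a
#' seasonal cycle), basin / intact-forest / open-water masks, annual
#' observed-AGB maps at three quantile levels, a bimonthly ENSO index,
#' a vegetation-stress series anti-correlated with it, per-year
#' primary-land fractions and a clearing-rate series - plus the
#' generator's own truth: the potential surface, the per-pixel
#' disturbance state, and the noise-free observations.
#'
#' Mechanics: the true potential is a fixed smooth function of the
#' annual-mean climate layers and latitude, shifted each year by an
#' ENSO-coupled anomaly (`enso_coupling` x winter composite) plus
#' independent interannual noise. Clearing is a per-pixel Bernoulli
#' process with spatially clustered probability (an "arc" of
#' deforestation), burnt in from `clearing_start_year`; cleared pixels
#' recover exponentially toward the potential at `regrowth_rate`.
#' Observed AGB is the potential times (1 - deficit fraction) plus
#' observation noise; open-water pixels keep a constant value across
#' years. The 5th/95th maps bracket the mean symmetrically
#' (`obs_spread`). Negative values are clipped at zero and counted.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world` object: a list of tibbles (`pixels`,
#'   `features`, `agb_obs`, `truth`, `mei`, `stress`,
#'   `deforestation_rate`, `primary_fraction`) plus the config, feature
#'   names, truth coefficients and clip counts.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  grid <- config$grid
  pix <- grid_pixels(grid)
  n <- nrow(pix)
  u <- (pix$lon - grid$lon_min) / (grid$lon_max - grid$lon_min)
  v <- (pix$lat - grid$lat_min) / (grid$lat_max - grid$lat_min)

  # --- masks -------------------------------------------------------------
  basin <- ((u - 0.5) / 0.45)^2 + ((v - 0.5) / 0.45)^2 <= 1
  # clearing propensity: smooth field plus a south-east gradient (the
  # "arc of deforestation"); intact landscapes are the low-propensity part
  propensity <- smooth_surface(u, v) + 1.5 * as.numeric(scale(u + (1 - v)))
  ifl <- basin & propensity <= stats::quantile(propensity[basin],
                                               config$ifl_fraction)
  w_field <- smooth_surface(u, v, k = 6, freq_max = 3)
  water <- basin &
    w_field >= stats::quantile(w_field[basin], 1 - config$water_fraction)
  if (config$water_fraction == 0) water <- rep(FALSE, n)
  # a usable world must leave enough intact pixels to determine at least
  # one leaf regression on each side of a split
  p_cont <- 12L * length(config$climate_vars) + 1L
  if (sum(ifl) < 4L * (p_cont + 1L)) {
    stop("grid too small: ", sum(ifl), " intact pixels cannot support ",
         "training with ", p_cont, " features", call. = FALSE)
  }
  pixels <- dplyr::mutate(pix, basin = basin, ifl = ifl, water = water,
                          propensity = propensity)

  # --- static monthly climatology ---------------------------------------
  clim_defaults <- list(pre = c(mean = 180, sd = 40, amp = 60),
                        tmp = c(mean = 26, sd = 1.5, amp = 2),
                        dtr = c(mean = 10, sd = 1, amp = 1.5))
  clim <- list()
  for (var in config$climate_vars) {
    cd <- clim_defaults[[var]]
    if (is.null(cd)) cd <- c(mean = 0, sd = 1, amp = 0.5)
    base <- cd[["mean"]] + cd[["sd"]] * smooth_surface(u, v, k = 12,
                                                       freq_max = 4)
    amp <- cd[["amp"]] * (0.6 + 0.4 * stats::plogis(smooth_surface(u, v)))
    phase <- stats::runif(1, 0, 12)
    for (m in 1:12) {
      layer <- base + amp * cos(2 * pi * (m - phase) / 12) +
        0.25 * cd[["sd"]] * smooth_surface(u, v, k = 4)
      if (var == "pre") layer <- pmax(layer, 0)
      clim[[sprintf("%s_%02d", var, m)]] <- layer
    }
  }
  features <- dplyr::bind_cols(
    pixels[c("pixel", "lat", "lon", "water")],
    tibble::as_tibble(clim)
  )
  feature_names <- c(names(clim), "lat")

  # --- true potential ----------------------------------------------------
  month_cols <- function(var) sprintf("%s_%02d", var, 1:12)
  ann_mean <- function(var) {
    if (var %in% config$climate_vars) {
      rowMeans(as.matrix(features[month_cols(var)]))
    } else {
      # missing variables enter the truth at their typical value, so the
      # surface stays defined for reduced-variable test worlds
      rep(clim_defaults[[var]][["mean"]], n)
    }
  }
  coef <- default_truth_coef()
  f_true <- true_potential_fun(coef)
  pot_base <- f_true(ann_mean("pre"), ann_mean("tmp"), ann_mean("dtr"),
                     pix$lat)
  clip_pot_base <- sum(pot_base < 0)
  pot_base <- pmax(pot_base, 0)

  # --- ENSO index and annual potential anomalies -------------------------
  years <- config$years
  ny <- length(years)
  n_bim <- ny * 12
  phi <- 0.85
  eps <- stats::rnorm(n_bim, sd = sqrt(1 - phi^2))
  mei_vals <- numeric(n_bim)
  mei_vals[1] <- stats::rnorm(1)
  for (t in 2:n_bim) mei_vals[t] <- phi * mei_vals[t - 1] + eps[t]
  mei <- tibble::tibble(
    year = rep(years, each = 12),
    bimonth = rep(1:12, times = ny),
    label = rep(bimonth_labels(), times = ny),
    value = mei_vals
  )
  mei_w <- winter_composite(mei, years)
  anom <- config$enso_coupling * mei_w$value +
    stats::rnorm(ny, sd = config$interannual_sd)
  pot <- outer(pot_base, anom, `+`) # n x ny
  clip_pot <- sum(pot < 0)
  pot <- pmax(pot, 0)

  # --- disturbance history ------------------------------------------------
  disturbed <- basin & !ifl & !water
  pw <- stats::plogis(1.2 * as.numeric(scale(propensity)))
  pw[!disturbed] <- 0
  p_clear <- rep(0, n)
  if (any(disturbed)) {
    p_clear[disturbed] <- pmin(
      config$disturbance_intensity * pw[disturbed] / mean(pw[disturbed]), 1)
  }
  d <- rep(0, n)      # current deficit fraction of potential
  cfrac <- rep(0, n)  # cumulative cleared fraction (no regrowth credit)
  step_year <- function(d, cfrac) {
    d <- d * (1 - config$regrowth_rate)
    hit <- disturbed & (stats::runif(n) < p_clear)
    f <- stats::runif(n, 0.4, 0.9) # drawn for all pixels: draw count fixed
    d[hit] <- d[hit] + f[hit] * (1 - d[hit])
    cfrac[hit] <- cfrac[hit] + f[hit] * (1 - cfrac[hit])
    list(d = d, cfrac = cfrac, hit = hit, f = f)
  }
  for (y in seq_len(years[1] - config$clearing_start_year)) {
    st <- step_year(d, cfrac)
    d <- st$d; cfrac <- st$cfrac
  }
  d_mat <- matrix(0, n, ny)
  c_mat <- matrix(0, n, ny)
  cleared_pg <- numeric(ny)
  d_mat[, 1] <- d; c_mat[, 1] <- cfrac
  area <- cell_area_ha(pix$lat, grid$resolution)
  for (t in 2:ny) {
    st <- step_year(d_mat[, t - 1], c_mat[, t - 1])
    d_mat[, t] <- st$d; c_mat[, t] <- st$cfrac
    # newly cleared deficit fraction = post-clearing minus post-regrowth state
    newly <- d_mat[, t] - d_mat[, t - 1] * (1 - config$regrowth_rate)
    newly[!st$hit] <- 0
    cleared_pg[t] <- sum(newly * pot[, t] * area) * 1e-9
  }
  cleared_pg[1] <- cleared_pg[2] # first study year has no preceding state

  # --- observations -------------------------------------------------------
  obs_clean <- pot * (1 - d_mat)
  obs_clean[ifl, ] <- pot[ifl, ]
  if (any(water)) {
    # constant in time, anchored at the static potential surface
    obs_clean[water, ] <- matrix(pot_base[water], sum(water), ny)
  }
  obs_clean[!basin, ] <- NA_real_
  noise <- matrix(stats::rnorm(n * ny, sd = config$obs_noise), n, ny)
  if (any(water)) noise[water, ] <- noise[water, 1] # constant among years
  obs_mean <- obs_clean + noise
  clip_obs <- sum(obs_mean < 0, na.rm = TRUE)
  obs_mean <- pmax(obs_mean, 0)

  level_maps <- list(
    q05 = obs_mean * (1 - config$obs_spread),
    mean = obs_mean,
    q95 = obs_mean * (1 + config$obs_spread)
  )
  agb_obs <- purrr::imap_dfr(level_maps, function(mat, lev) {
    tibble::tibble(
      pixel = rep(pix$pixel, times = ny),
      year = rep(years, each = n),
      level = lev,
      agb = as.vector(mat)
    )
  })

  truth <- tibble::tibble(
    pixel = rep(pix$pixel, times = ny),
    year = rep(years, each = n),
    potential = as.vector(pot),
    obs_clean = as.vector(obs_clean),
    deficit = as.vector(pot - obs_clean)
  )

  primary_fraction <- tibble::tibble(
    pixel = rep(pix$pixel, times = ny),
    year = rep(years, each = n),
    value = as.vector(ifelse(rep(basin, ny), 1 - c_mat, NA_real_))
  )

  stress <- zscore(tibble::tibble(
    year = years,
    value = -0.8 * mei_w$value + stats::rnorm(ny, sd = 0.6)
  ))
  defor_noise <- stats::rnorm(ny, sd = 0.05 * max(stats::sd(cleared_pg), 1e-12))
  deforestation_rate <- tibble::tibble(year = years,
                                       value = cleared_pg + defor_noise)

  structure(
    list(config = config, grid = grid, pixels = pixels, features = features,
         feature_names = feature_names, agb_obs = agb_obs, truth = truth,
         mei = mei, stress = stress,
         deforestation_rate = deforestation_rate,
         primary_fraction = primary_fraction,
         truth_coefficients = coef,
         clip_counts = c(potential_base = clip_pot_base,
                         potential = clip_pot, observation = clip_obs)),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d x %d grid, years %d-%d, seed %d\n",
    x$grid$n_lat, x$grid$n_lon, min(x$config$years), max(x$config$years),
    x$config$seed))
  cat(sprintf("  basin %d px, IFL %d px, water %d px, disturbed %d px\n",
              sum(x$pixels$basin), sum(x$pixels$ifl), sum(x$pixels$water),
              sum(x$pixels$basin & !x$pixels$ifl & !x$pixels$water)))
  invisible(x)
}

#' Ground-truth summary of a synthetic world
#'
#' Recomputes, from the generator's truth fields and with the same
#' area-weighted aggregation the pipeline uses, the quantities recovery
#' tests compare against: the true deficit series over the disturbed
#' zone (Pg C), its linear trend, and the injected ENSO correlation
#' (winter composite vs detrended annual change in true potential
#' totals).
#'
#' @param world A `synthetic_world`.
#' @return A list: `deficit_series` (tibble `year`, `value`),
#'   `pot_series`, `obs_series`, `trend` (one-row tibble), `enso`
#'   (one-row tibble `r`, `n`, `p`), `coefficients`, `clip_counts`.
#' @export
truth_report <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  res <- world$grid$resolution
  px <- world$pixels
  disturbed <- px$pixel[px$basin & !px$ifl]
  tr <- dplyr::left_join(world$truth,
                         px[c("pixel", "lat")], by = "pixel")
  tr <- tr[tr$pixel %in% disturbed, ]
  series <- tr |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      pot = total_pg(.data$potential, .data$lat, res),
      obs = total_pg(.data$obs_clean, .data$lat, res),
      .groups = "drop"
    )
  deficit_series <- tibble::tibble(year = series$year,
                                   value = series$pot - series$obs)
  pot_series <- tibble::tibble(year = series$year, value = series$pot)
  obs_series <- tibble::tibble(year = series$year, value = series$obs)
  mei_w <- winter_composite(world$mei)
  # a flat potential series (no coupling, no interannual noise) has no
  # defined correlation; report it as degenerate rather than failing
  enso <- tryCatch(
    correlate(mei_w, detrend(annual_delta(pot_series))),
    error = function(e) tibble::tibble(r = NA_real_,
                                       n = nrow(pot_series) - 1L,
                                       p = NA_real_)
  )
  list(
    deficit_series = deficit_series,
    pot_series = pot_series,
    obs_series = obs_series,
    trend = linear_trend(deficit_series),
    enso = enso,
    coefficients = world$truth_coefficients,
    clip_counts = world$clip_counts
  )
}

#' Write a synthetic world bundle to a directory
#'
#' Rasters go to the package's plain-text raster format, series to CSV.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  px <- world$pixels
  masks <- as_raster(px[c("lat", "lon", "basin", "ifl", "water")],
                     world$grid, units = "flag")
  write_raster(masks, file.path(dir, "masks.csv"))
  clim <- as_raster(world$features[c("lat", "lon", world$feature_names[world$feature_names != "lat"])],
                    world$grid, units = "climatology")
  write_raster(clim, file.path(dir, "climatology.csv"))
  obs <- dplyr::left_join(world$agb_obs, px[c("pixel", "lat", "lon")],
                          by = "pixel")
  readr::write_csv(obs[c("lat", "lon", "year", "level", "agb")],
                   file.path(dir, "agb_obs.csv"))
  write_series(world$mei, file.path(dir, "mei.csv"))
  write_series(world$stress, file.path(dir, "stress.csv"))
  write_series(world$deforestation_rate,
               file.path(dir, "deforestation_rate.csv"))
  readr::write_csv(world$primary_fraction,
                   file.path(dir, "primary_fraction.csv"))
  invisible(dir)
}
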
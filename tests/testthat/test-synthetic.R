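test_that("worlds are bit-identical given a seed and differ across seeds", {
  w1 <- small_world(seed = 3)
  w2 <- small_world(seed = 3)
  expect_identical(w1$agb_obs, w2$agb_obs)
  expect_identical(w1$features, w2$features)
  expect_identical(w1$mei, w2$mei)
  w3 <- small_world(seed = 4)
  expect_false(identical(w1$agb_obs$agb, w3$agb_obs$agb))
})

test_that("masks nest correctly and hit the intact-fraction target", {
  w <- generate_world(world_config(seed = 5))
  px <- w$pixels
  expect_true(all(px$basin[px$ifl]))
  expect_true(all(px$basin[px$water]))
  frac <- sum(px$ifl) / sum(px$basin)
  expect_lt(abs(frac - 0.55), 0.02)
  # disturbed zone is basin minus intact by construction
  expect_identical(px$basin & !px$ifl,
                   !px$ifl & px$basin)
})

test_that("the no-disturbance, no-noise limit collapses to the truth", {
  w <- small_world(seed = 7, disturbance_intensity = 0, obs_spread = 0,
                   obs_noise = 0, water_fraction = 0)
  obs <- w$agb_obs[w$agb_obs$level == "mean", ]
  m <- dplyr::inner_join(obs, w$truth, by = c("pixel", "year"))
  m <- m[!is.na(m$agb), ]
  expect_equal(m$agb, m$potential, tolerance = 1e-12)
  tr <- truth_report(w)
  expect_true(all(abs(tr$deficit_series$value) < 1e-12))
  # all three levels coincide when the spread is zero
  wide <- tidyr::pivot_wider(w$agb_obs, names_from = "level",
                             values_from = "agb")
  expect_identical(wide$q05, wide$mean)
  expect_identical(wide$q95, wide$mean)
})

test_that("percentile levels bracket the mean symmetrically", {
  w <- small_world(seed = 8)
  wide <- tidyr::pivot_wider(w$agb_obs, names_from = "level",
                             values_from = "agb")
  wide <- wide[!is.na(wide$mean), ]
  expect_true(all(wide$q05 <= wide$mean & wide$mean <= wide$q95))
  expect_equal((wide$q05 + wide$q95) / 2, wide$mean, tolerance = 1e-10)
})

test_that("no negative biomass is emitted and clips are counted", {
  w <- small_world(seed = 9, obs_noise = 40) # heavy noise forces clipping
  expect_true(all(w$agb_obs$agb >= 0, na.rm = TRUE))
  expect_named(w$clip_counts,
               c("potential_base", "potential", "observation"))
  expect_gt(w$clip_counts[["observation"]], 0)
})

test_that("open-water observations are constant across years", {
  w <- generate_world(world_config(seed = 10))
  water_px <- w$pixels$pixel[w$pixels$water]
  expect_gt(length(water_px), 0)
  obs <- w$agb_obs[w$agb_obs$level == "mean" &
                     w$agb_obs$pixel %in% water_px, ]
  spread <- tapply(obs$agb, obs$pixel, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("intact pixels sit at potential plus noise; disturbed sit below", {
  w <- small_world(seed = 11)
  obs <- w$agb_obs[w$agb_obs$level == "mean", ]
  m <- dplyr::inner_join(obs, w$truth, by = c("pixel", "year"))
  m <- dplyr::inner_join(m, w$pixels[c("pixel", "ifl", "basin", "water")],
                         by = "pixel")
  intact <- m[m$ifl & !m$water, ]
  expect_lt(abs(mean(intact$agb - intact$potential)), 1)
  disturbed <- m[m$basin & !m$ifl & !m$water, ]
  # deficit non-negative in expectation under active disturbance
  expect_gt(mean(disturbed$potential - disturbed$agb), 0)
  expect_true(all(m$deficit[m$basin & !m$water] >= -1e-9 |
                    is.na(m$deficit[m$basin & !m$water])))
})

test_that("zero regrowth makes the deficit monotone under steady clearing", {
  w <- small_world(seed = 12, regrowth_rate = 0, enso_coupling = 0,
                   interannual_sd = 0, obs_noise = 0, water_fraction = 0)
  tr <- truth_report(w)
  expect_true(all(diff(tr$deficit_series$value) >= -1e-12))
})

test_that("the truth report is self-consistent and carries the ENSO signal", {
  w <- generate_world(world_config(seed = 13))
  tr <- truth_report(w)
  expect_equal(tr$deficit_series$value,
               tr$pot_series$value - tr$obs_series$value,
               tolerance = 1e-12)
  # injected negative coupling shows up as a negative correlation
  expect_lt(tr$enso$r, 0)
  # rising deficit under the default disturbance settings
  expect_gt(tr$trend$slope, 0)
})

test_that("primary-land fraction declines only where clearing happened", {
  w <- small_world(seed = 14)
  pf <- w$primary_fraction[!is.na(w$primary_fraction$value), ]
  by_px <- tapply(pf$value, pf$pixel, function(v) all(diff(v) <= 1e-12))
  expect_true(all(by_px))
  ifl_px <- w$pixels$pixel[w$pixels$ifl]
  expect_true(all(pf$value[pf$pixel %in% ifl_px] == 1))
})

test_that("a degenerate grid is rejected before any compute", {
  tiny <- world_config(grid = grid_spec(-1, 0, -1, 0, 0.25))
  expect_error(generate_world(tiny), "training")
})

test_that("world bundles write to plain-text files and read back", {
  w <- small_world(seed = 15)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_true(all(file.exists(file.path(
    dir, c("masks.csv", "climatology.csv", "agb_obs.csv", "mei.csv",
           "stress.csv", "deforestation_rate.csv",
           "primary_fraction.csv")))))
  masks <- read_raster(file.path(dir, "masks.csv"))
  expect_identical(sum(masks$ifl), sum(w$pixels$ifl))
})
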
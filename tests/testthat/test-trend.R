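test_that("linear trends recover exact lines and flag constant series", {
  s <- tibble::tibble(year = 1993:2012, value = 2.5 * (1993:2012) - 100)
  tr <- linear_trend(s)
  expect_equal(tr$slope, 2.5, tolerance = 1e-10)
  expect_equal(tr$r, 1, tolerance = 1e-10)
  flat <- tibble::tibble(year = 1993:2012, value = 7)
  trf <- linear_trend(flat)
  expect_true(trf$degenerate)
  expect_identical(trf$slope, 0)
  expect_identical(trf$r, 0)
  expect_error(linear_trend(s, c(1980, 2000)), "outside")
})

test_that("windowed trends separate a linear segment from a plateau", {
  set.seed(1)
  years <- 1993:2012
  value <- ifelse(years <= 2005, 0.1 * (years - 1993),
                  0.1 * (2005 - 1993)) + rnorm(20, sd = 0.01)
  s <- tibble::tibble(year = years, value = value)
  pre <- linear_trend(s, c(1993, 2005))
  post <- linear_trend(s, c(2005, 2012))
  expect_gt(pre$r, 0.99)
  expect_lt(abs(post$slope), 0.01)
})

test_that("annual deltas telescope and reject gappy series", {
  s <- tibble::tibble(year = 1993:2012,
                      value = seq(26.3, 24.1, length.out = 20))
  d <- annual_delta(s)
  expect_identical(d$year, 1994:2012)
  expect_equal(sum(d$value), 24.1 - 26.3, tolerance = 1e-12)
  expect_equal(d$value, rep(d$value[1], 19), tolerance = 1e-12)
  flat <- tibble::tibble(year = 1:5, value = 3)
  expect_true(all(annual_delta(flat)$value == 0))
  gappy <- tibble::tibble(year = c(1993, 1995, 1996), value = 1:3)
  expect_error(annual_delta(gappy), "gaps")
})

test_that("detrending is idempotent, mean-zero and kills pure trends", {
  set.seed(2)
  s <- tibble::tibble(year = 1993:2012,
                      value = 3 * (1993:2012) + rnorm(20))
  d1 <- detrend(s)
  expect_lt(abs(mean(d1$value)), 1e-10)
  expect_lt(abs(cor(d1$value, d1$year)), 1e-10)
  d2 <- detrend(d1)
  expect_equal(d2$value, d1$value, tolerance = 1e-10)
  pure <- tibble::tibble(year = 1:10, value = 2 * (1:10) + 5)
  expect_true(all(abs(detrend(pure)$value) < 1e-10))
  expect_lte(var(d1$value), var(s$value))
})

test_that("winter composites average the four winter bimonths", {
  mei <- tidyr::expand_grid(year = 2000:2001, bimonth = 1:12)
  mei$value <- 7
  expect_equal(winter_composite(mei)$value, c(7, 7))
  mei$value <- ifelse(mei$year == 2000 & mei$bimonth <= 4,
                      mei$bimonth, 0)
  expect_equal(winter_composite(mei, 2000)$value, 2.5)
  # injected warm winter: all four above 1 forces the composite above 1
  mei$value <- ifelse(mei$bimonth <= 4, 1.3, -2)
  expect_true(all(winter_composite(mei)$value > 1))
  incomplete <- mei[!(mei$year == 2001 & mei$bimonth == 2), ]
  expect_error(winter_composite(incomplete, 2001), "Jan/Feb")
})

test_that("correlation handles identity, sign flips and affine maps", {
  set.seed(3)
  a <- tibble::tibble(year = 1:20, value = rnorm(20))
  expect_equal(correlate(a, a)$r, 1, tolerance = 1e-12)
  neg <- dplyr::mutate(a, value = -value)
  expect_equal(correlate(a, neg)$r, -1, tolerance = 1e-12)
  b <- tibble::tibble(year = 1:20, value = rnorm(20))
  expect_equal(correlate(a, b)$r, correlate(b, a)$r, tolerance = 1e-15)
  aff <- dplyr::mutate(b, value = 3 * value - 7)
  expect_equal(correlate(a, aff)$r, correlate(a, b)$r, tolerance = 1e-12)
  short <- tibble::tibble(year = 1:2, value = 1:2)
  expect_error(correlate(a, short), "3 common")
  flat <- tibble::tibble(year = 1:20, value = 1)
  expect_error(correlate(a, flat), "variance")
})

test_that("series align on overlapping labels only", {
  a <- tibble::tibble(year = 1:10, value = 1:10)
  b <- tibble::tibble(year = 6:15, value = 6:15)
  res <- correlate(a, b)
  expect_identical(res$n, 5L)
  expect_equal(res$r, 1, tolerance = 1e-12)
})

test_that("spatial correlation is scale- and location-invariant", {
  set.seed(4)
  g <- grid_spec(-5, 0, 10, 15)
  m1 <- dplyr::mutate(grid_pixels(g), value = rnorm(400))
  m2 <- dplyr::mutate(m1, value = 2 * value)
  expect_equal(spatial_correlation(m1, m2)$r, 1, tolerance = 1e-12)
  m3 <- dplyr::mutate(m1, value = value + 5)
  expect_equal(spatial_correlation(m1, m3)$r, 1, tolerance = 1e-12)
  flat <- dplyr::mutate(m1, value = 3)
  expect_true(spatial_correlation(m1, flat)$degenerate)
  # masking restricts the sample
  res <- spatial_correlation(m1, m2, mask = m1$lon < 12.5)
  expect_identical(res$n, sum(m1$lon < 12.5))
})

test_that("pixelwise temporal correlation finds monotone opposition", {
  px <- tibble::tibble(pixel = 1:3, lat = 0.125, lon = c(1, 2, 3) - 0.875)
  years <- 2000:2009
  x <- tidyr::expand_grid(px, year = years) |>
    dplyr::mutate(value = dplyr::case_when(
      pixel == 1 ~ 1 - 0.05 * (year - 2000), # declining primary fraction
      pixel == 2 ~ 0.5,                       # constant: degenerate
      TRUE ~ 0.3 + 0.02 * (year - 2000)
    ))
  y <- tidyr::expand_grid(px, year = years) |>
    dplyr::mutate(value = dplyr::case_when(
      pixel == 1 ~ 10 + 2 * (year - 2000),   # rising deficit
      pixel == 2 ~ 5 + 1 * (year - 2000),
      TRUE ~ 8 - 0.5 * (year - 2000)
    ))
  res <- pixelwise_temporal_correlation(x, y)
  r1 <- res[res$pixel == 1, ]
  expect_equal(r1$r, -1, tolerance = 1e-12)
  expect_true(r1$significant)
  r2 <- res[res$pixel == 2, ]
  expect_true(r2$degenerate)
  expect_false(r2$significant)
})

test_that("z-scores standardise and ignore affine transforms", {
  s <- tibble::tibble(year = 1:10, value = rnorm(10, 50, 5))
  z <- zscore(s)
  expect_lt(abs(mean(z$value)), 1e-12)
  expect_equal(sd(z$value), 1, tolerance = 1e-12)
  aff <- dplyr::mutate(s, value = 4 * value - 3)
  expect_equal(zscore(aff)$value, z$value, tolerance = 1e-12)
  two <- tibble::tibble(year = 1:2, value = c(0, 1))
  expect_equal(zscore(two)$value,
               c(-0.7071067811865475, 0.7071067811865475),
               tolerance = 1e-12)
  expect_error(zscore(tibble::tibble(year = 1:5, value = 2)), "variance")
})
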
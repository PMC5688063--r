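#' @importFrom rlang .data
NULL

# Pearson correlation with two-sided t-test p-value; the scalar helper
# behind correlate() and the map operations.
pearson_rp <- function(x, y) {
  n <- length(x)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (n < 3 || is.na(sx) || is.na(sy) || sx == 0 || sy == 0) {
    return(list(r = NA_real_, n = n, p = NA_real_, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), n = n, p = ct$p.value, degenerate = FALSE)
}

check_series <- function(series, label = "year") {
  stopifnot(is.data.frame(series),
            all(c(label, "value") %in% names(series)))
  if (anyDuplicated(series[[label]]) > 0) {
    stop("duplicate time labels in series", call. = FALSE)
  }
  dplyr::arrange(series, .data[[label]])
}

#' Ordinary least-squares trend over a year window
#'
#' Fits `value ~ year` over the requested window and reports the slope,
#' intercept and the Pearson correlation of value with year. A constant
#' series has no defined correlation; it is reported as `r = 0` with the
#' `degenerate` flag set (and slope 0), never as an error.
#'
#' @param series Tibble with `year` and `value` columns.
#' @param window Optional length-2 year range `c(first, last)`
#'   (inclusive); default is the full series.
#' @return One-row tibble: `slope`, `intercept`, `r`, `p`, `n`,
#'   `degenerate`.
#' @export
linear_trend <- function(series, window = NULL) {
  series <- check_series(series)
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    if (window[1] < min(series$year) || window[2] > max(series$year)) {
      stop("trend window extends outside the series years", call. = FALSE)
    }
    series <- dplyr::filter(series, .data$year >= window[1],
                            .data$year <= window[2])
  }
  if (nrow(series) < 3) stop("need >= 3 points for a trend", call. = FALSE)
  rp <- pearson_rp(series$year, series$value)
  if (rp$degenerate) {
    return(tibble::tibble(slope = 0, intercept = mean(series$value),
                          r = 0, p = NA_real_, n = nrow(series),
                          degenerate = TRUE))
  }
  fit <- stats::lm(value ~ year, data = series)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = rp$r, p = rp$p, n = rp$n, degenerate = FALSE)
}

#' Annual first differences of a series
#'
#' `delta(y) = value(y) - value(y - 1)`, labelled by the later year.
#' The series must cover consecutive years; a gap is an error, not an
#' implicit interpolation.
#'
#' @param series Tibble with `year` and `value`.
#' @return Tibble with `year` and `value` (the differences), one row
#'   shorter than the input.
#' @export
annual_delta <- function(series) {
  series <- check_series(series)
  if (nrow(series) < 2) stop("need >= 2 points for deltas", call. = FALSE)
  if (any(diff(series$year) != 1)) {
    stop("series has gaps in years; deltas are defined on consecutive years",
         call. = FALSE)
  }
  tibble::tibble(year = series$year[-1], value = diff(series$value))
}

#' Remove the linear time trend from a series
#'
#' Returns the residuals of OLS on time. Residuals have zero mean and
#' zero correlation with time (to 1e-10), and the operation is
#' idempotent.
#'
#' @param series Tibble with `year` and `value`.
#' @return Tibble with `year` and `value` (the residuals).
#' @export
detrend <- function(series) {
  series <- check_series(series)
  if (nrow(series) < 3) stop("need >= 3 points to detrend", call. = FALSE)
  res <- stats::residuals(stats::lm(value ~ year, data = series))
  tibble::tibble(year = series$year, value = unname(res))
}

#' Standard bimonthly labels (Dec/Jan .. Nov/Dec)
#' @return Character vector of the 12 bimonthly labels in year order.
#' @export
bimonth_labels <- function() {
  m <- c("Dec", "Jan", "Feb", "Mar", "Apr", "May", "Jun", "Jul", "Aug",
         "Sep", "Oct", "Nov", "Dec")
  paste(m[-13], m[-1], sep = "/")
}

#' Boreal-winter composite of a bimonthly ENSO index
#'
#' The winter composite for calendar year Y is the arithmetic mean of the
#' four bimonthly values Dec/Jan through Mar/Apr, where Dec/Jan is
#' assigned to the year containing the January (so Dec(Y-1)/Jan(Y)
#' belongs to year Y). The winter ENSO peak precedes and overlaps the
#' growing season that shapes that year's biomass stocks.
#'
#' @param mei Tibble with `year`, `bimonth` (1..12, in [bimonth_labels()]
#'   order) and `value`.
#' @param years Years to composite; default all years in `mei` with the
#'   four winter bimonths present.
#' @return Tibble with `year` and `value` (the composite).
#' @export
winter_composite <- function(mei, years = NULL) {
  stopifnot(is.data.frame(mei), all(c("year", "bimonth", "value") %in% names(mei)))
  if (is.null(years)) years <- sort(unique(mei$year))
  labs <- bimonth_labels()
  out <- purrr::map_dbl(years, function(y) {
    winter <- dplyr::filter(mei, .data$year == y, .data$bimonth %in% 1:4)
    present <- sort(unique(winter$bimonth))
    if (!identical(present, 1:4)) {
      miss <- setdiff(1:4, present)
      stop("year ", y, " is missing winter bimonth(s): ",
           paste(labs[miss], collapse = ", "), call. = FALSE)
    }
    mean(winter$value)
  })
  tibble::tibble(year = years, value = out)
}

#' Pearson correlation of two series on their common labels
#'
#' Series are aligned on the label column; the correlation and its
#' two-sided p-value (t-distributed with n - 2 degrees of freedom) are
#' computed on the intersection. Zero variance in either aligned series
#' is an error in this scalar context.
#'
#' @param a,b Tibbles with a shared label column and `value`.
#' @param by Label column name (default `"year"`).
#' @return One-row tibble: `r`, `n`, `p`.
#' @export
correlate <- function(a, b, by = "year") {
  a <- check_series(a, by); b <- check_series(b, by)
  m <- dplyr::inner_join(a, b, by = by, suffix = c("_a", "_b"))
  m <- m[stats::complete.cases(m[c("value_a", "value_b")]), ]
  if (nrow(m) < 3) {
    stop("fewer than 3 common labels between the series", call. = FALSE)
  }
  rp <- pearson_rp(m$value_a, m$value_b)
  if (rp$degenerate) {
    stop("zero variance in one of the aligned series", call. = FALSE)
  }
  tibble::tibble(r = rp$r, n = rp$n, p = rp$p)
}

#' Spatial correlation of two raster layers
#'
#' Pearson correlation across pixels (each non-missing pixel is one
#' unweighted sample) between two layers joined on `lat`/`lon`.
#'
#' @param map1,map2 Raster tibbles with `lat`, `lon` and a value column.
#' @param mask Optional logical vector (aligned with `map1`'s rows) or a
#'   logical column name present in `map1`.
#' @param value Value column name in both maps (default `"value"`).
#' @return One-row tibble: `r`, `n`, `p`, `degenerate`.
#' @export
spatial_correlation <- function(map1, map2, mask = NULL, value = "value") {
  stopifnot(all(c("lat", "lon", value) %in% names(map1)),
            all(c("lat", "lon", value) %in% names(map2)))
  if (is.character(mask) && length(mask) == 1) mask <- map1[[mask]]
  if (is.null(mask)) mask <- TRUE
  m1 <- map1[rep_len(as.logical(mask), nrow(map1)), c("lat", "lon", value)]
  m <- dplyr::inner_join(m1, map2[c("lat", "lon", value)],
                         by = c("lat", "lon"), suffix = c("_1", "_2"))
  m <- m[stats::complete.cases(m[c(paste0(value, "_1"), paste0(value, "_2"))]), ]
  if (nrow(m) < 3) {
    stop("fewer than 3 common non-missing pixels", call. = FALSE)
  }
  rp <- pearson_rp(m[[paste0(value, "_1")]], m[[paste0(value, "_2")]])
  tibble::tibble(r = rp$r, n = rp$n, p = rp$p, degenerate = rp$degenerate)
}

#' Per-pixel temporal correlation between two annual field stacks
#'
#' For each pixel with at least 3 years where both stacks are defined,
#' the Pearson correlation over years and its two-sided p-value are
#' computed; `significant` marks p < alpha with no multiple-testing
#' correction (a deliberately liberal convention: each pixel is read as
#' its own test). Pixels with zero variance in either stack are flagged
#' degenerate and never significant.
#'
#' @param x,y Tibbles with `pixel`, `lat`, `lon`, `year`, `value`.
#' @param alpha Significance level for the mask (default 0.05).
#' @return Tibble with one row per qualifying pixel: `pixel`, `lat`,
#'   `lon`, `r`, `n`, `p`, `degenerate`, `significant`.
#' @export
pixelwise_temporal_correlation <- function(x, y, alpha = 0.05) {
  need <- c("pixel", "lat", "lon", "year", "value")
  stopifnot(all(need %in% names(x)), all(need %in% names(y)))
  m <- dplyr::inner_join(x[need], y[need],
                         by = c("pixel", "lat", "lon", "year"),
                         suffix = c("_x", "_y"))
  m <- m[stats::complete.cases(m[c("value_x", "value_y")]), ]
  out <- m |>
    dplyr::group_by(.data$pixel, .data$lat, .data$lon) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(
      res = list(pearson_rp(.data$value_x, .data$value_y)),
      .groups = "drop"
    )
  out |>
    dplyr::mutate(
      r = purrr::map_dbl(.data$res, "r"),
      n = purrr::map_int(.data$res, ~ as.integer(.x$n)),
      p = purrr::map_dbl(.data$res, "p"),
      degenerate = purrr::map_lgl(.data$res, "degenerate"),
      significant = !.data$degenerate & !is.na(.data$p) & .data$p < alpha
    ) |>
    dplyr::select(-"res")
}

#' Standardise a series to z-scores
#'
#' `(x - mean(x)) / sd(x)` with the sample (n - 1) standard deviation.
#'
#' @param series Tibble with a label column and `value`.
#' @param by Label column name (default `"year"`).
#' @return Tibble with the label column and standardised `value`.
#' @export
zscore <- function(series, by = "year") {
  series <- check_series(series, by)
  if (nrow(series) < 2) stop("need >= 2 points to standardise", call. = FALSE)
  s <- stats::sd(series$value)
  if (is.na(s) || s == 0) stop("zero variance: z-score undefined", call. = FALSE)
  series$value <- (series$value - mean(series$value)) / s
  series
}
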
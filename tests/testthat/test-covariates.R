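fire_at <- function(x, y, date) {
  data.frame(centroid_x = x, centroid_y = y,
             ignition_date = day_from_date(date))
}

test_that("monthly rainfall is a containing-cell lookup", {
  rain <- uniform_rain(100, 2001:2006)
  f <- fire_at(7100, 2900, "2005-07-15")
  expect_equal(monthly_rain_at(f, rain), 100)
  # half-open convention: a boundary point belongs to the cell above it
  g <- rain
  g$arr[1, 1, ] <- 1; g$arr[1, 2, ] <- 2
  expect_equal(monthly_rain_at(fire_at(5000, 0, "2005-07-15"), g), 2)
  expect_error(monthly_rain_at(fire_at(-10, 0, "2005-07-15"), rain),
               "outside")
})

test_that("gradient fields match a direct nearest-cell oracle", {
  set.seed(4)
  rain <- uniform_rain(0, 2001:2002)
  rain$arr[] <- stats::runif(length(rain$arr))
  for (k in 1:100) {
    x <- runif(1, 0, 3 * 5000 - 1e-6); y <- runif(1, 0, 3 * 5000 - 1e-6)
    f <- fire_at(x, y, "2002-03-10")
    slice <- which(rain$time$year == 2002 & rain$time$month == 3)
    want <- rain$arr[floor(y / 5000) + 1, floor(x / 5000) + 1, slice]
    expect_equal(monthly_rain_at(f, rain), want)
  }
})

test_that("cumulative rainfall follows the calendar month-enumeration oracle", {
  rain <- uniform_rain(100, 2001:2010)
  # fire in January of rainfall year 2006 (January 2006); default mode
  # window: Oct 2004 (start of rainfall year 2005) .. Dec 2005 = 15 months
  f <- fire_at(7100, 2900, "2006-01-15")
  expect_equal(cumulative_rain_at(f, rain), 15 * 100)
  # two-rainfall-year mode adds exactly one rainfall year's sum
  expect_equal(cumulative_rain_at(f, rain, "two_rainfall_years"),
               15 * 100 + 12 * 100)
  # all-zero series sums to zero
  zero <- uniform_rain(0, 2001:2010)
  expect_equal(cumulative_rain_at(f, zero), 0)
  # window before the series start errors
  early <- fire_at(7100, 2900, "2002-01-15")
  expect_error(cumulative_rain_at(early, rain), "precedes")
})

test_that("cumulative rainfall is non-decreasing in window length", {
  set.seed(8)
  rain <- uniform_rain(0, 2001:2010)
  rain$arr[] <- stats::rexp(length(rain$arr), 1 / 50)
  for (d in c("2006-03-10", "2008-11-02", "2010-06-30")) {
    f <- fire_at(2000, 2000, d)
    expect_gte(cumulative_rain_at(f, rain, "two_rainfall_years"),
               cumulative_rain_at(f, rain, "prev_rainfall_year_start"))
  }
})

test_that("annual rainfall trends recover the planted rate of change", {
  cfg <- tiny_cfg(20L, 20L, seed = 21L, years = 2001:2014)
  flat <- generate_rainfall(cfg, west_east_gradient = 0, trend = 0,
                            noise_sdlog = 0)
  tr0 <- annual_rainfall_trend(flat)
  expect_true(all(abs(tr0$slope$values) < 1e-9))
  trended <- generate_rainfall(cfg, west_east_gradient = 0, trend = 5,
                               noise_sdlog = 0.1)
  tr <- annual_rainfall_trend(trended)
  m <- mean(tr$slope$values)
  se <- sd(tr$slope$values) / sqrt(length(tr$slope$values))
  expect_lt(abs(m - 5), 3 * se + 0.5)
  # most pixels should show the planted increase
  expect_gt(mean(tr$slope$values > 0), 0.9)
  expect_error(annual_rainfall_trend(uniform_rain(1, 2001:2002)),
               "3 complete years")
})

test_that("per-pixel rainfall slopes equal an independent lm oracle", {
  cfg <- tiny_cfg(6L, 6L, seed = 33L, years = 2001:2010)
  rain <- generate_rainfall(cfg, trend = 3, noise_sdlog = 0.2,
                            rain_pixel_factor = 1)
  tr <- annual_rainfall_trend(rain)
  ann <- annual_rainfall(rain)
  years <- as.integer(names(ann))
  for (cell in list(c(1L, 1L), c(3L, 4L), c(6L, 6L))) {
    y <- vapply(ann, function(r) r$values[cell[1], cell[2]], 0)
    fit <- stats::lm(y ~ I(years - years[1]))
    expect_equal(tr$slope$values[cell[1], cell[2]],
                 unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(tr$intercept$values[cell[1], cell[2]],
                 unname(coef(fit)[1]), tolerance = 1e-10)
  }
})

test_that("static extraction handles uniform, patterned and nodata cells", {
  surf <- fr_raster(matrix(7, 4, 4), pixel_size = 1000)
  f <- fire_at(1500, 2500, "2005-01-01")
  expect_equal(extract_static(f, surf), 7)
  # checkerboard vs direct lookup oracle
  chk <- fr_raster(outer(1:8, 1:8, function(i, j) (i + j) %% 2),
                   pixel_size = 500)
  set.seed(5)
  for (k in 1:50) {
    x <- runif(1, 0, 4000 - 1e-9); y <- runif(1, 0, 4000 - 1e-9)
    expect_equal(extract_static(fire_at(x, y, "2005-01-01"), chk),
                 chk$values[floor(y / 500) + 1, floor(x / 500) + 1])
  }
  hole <- surf
  hole$values[2, 2] <- NA
  expect_warning(v <- extract_static(fire_at(1500, 1500, "2005-01-01"), hole),
                 "nodata")
  expect_true(is.na(v))
  # categorical surfaces return labels
  soil <- fr_raster(matrix(c("vertisol", "andosol"), 2, 2), pixel_size = 1000)
  expect_identical(fr_value_at(soil, 500, 500), "vertisol")
})

test_that("the covariate table assembles per event with flagged gaps", {
  cfg <- tiny_cfg(20L, 20L, seed = 6L, years = 2001:2004)
  b <- generate_burn_history(cfg, 3L, 4L)
  fl <- delineate_fires(b$records, cfg)
  rain <- generate_rainfall(cfg)
  cv <- build_fire_covariates(fl$events, rain = rain)
  expect_identical(nrow(cv), nrow(fl$events))
  expect_true(all(c("monthly_rain", "cumulative_rain") %in% names(cv)))
  # 2001 fires predate the cumulative window: missing, later fires present
  first <- cv$cumulative_rain[fl$events$calendar_year == 2001]
  later <- cv$cumulative_rain[fl$events$calendar_year >= 2003]
  expect_true(all(is.na(first)))
  expect_true(all(!is.na(later)))
})
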
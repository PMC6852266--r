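#' Rainfall in the month of a fire
#'
#' Value of the rainfall cell containing the fire centroid, for the ignition
#' month (half-open cell convention; an error if the centroid falls outside
#' the rainfall grid).
#'
#' @param fire one row of the event table from [compute_characteristics()]
#'   (needs `centroid_x`, `centroid_y`, `ignition_date`).
#' @param series an [fr_series()] of monthly rainfall.
#' @return rainfall, mm.
#' @export
monthly_rain_at <- function(fire, series) {
  fr_series_at(series, fire$centroid_x, fire$centroid_y,
               calendar_year_of(fire$ignition_date),
               month_of(fire$ignition_date))
}

#' Cumulative rainfall before a fire
#'
#' Sum of monthly rainfall at the fire centroid from a window start through
#' the month *preceding* ignition (the ignition month is excluded so that
#' monthly and cumulative rainfall partition the record). Two window
#' conventions are supported: `prev_rainfall_year_start` begins at the start
#' of the rainfall year before the fire's (the default), and
#' `two_rainfall_years` begins one rainfall year earlier still; the two
#' differ by exactly one full rainfall year's total.
#'
#' @inheritParams monthly_rain_at
#' @param mode window convention.
#' @return cumulative rainfall, mm.
#' @export
cumulative_rain_at <- function(fire, series,
                               mode = c("prev_rainfall_year_start",
                                        "two_rainfall_years")) {
  mode <- match.arg(mode)
  ry <- rainfall_year(fire$ignition_date)
  start_label <- if (mode == "prev_rainfall_year_start") ry - 1L else ry - 2L
  start_day <- rainfall_year_start(start_label)
  y0 <- calendar_year_of(start_day); m0 <- month_of(start_day)
  ign_y <- calendar_year_of(fire$ignition_date)
  ign_m <- month_of(fire$ignition_date)
  # through the month before ignition
  end <- ign_y * 12L + (ign_m - 1L) - 1L
  y1 <- end %/% 12L; m1 <- end %% 12L + 1L
  if (y0 < series$time$year[1] ||
      (y0 == series$time$year[1] && m0 < series$time$month[1]))
    stop("cumulative-rainfall window precedes the start of the series")
  months <- month_seq(y0, m0, y1, m1)
  if (nrow(months) == 0L) return(0)
  sum(vapply(seq_len(nrow(months)), function(k) {
    fr_series_at(series, fire$centroid_x, fire$centroid_y,
                 months$year[k], months$month[k])
  }, 0))
}

#' Per-pixel annual rainfall totals
#'
#' @param series an [fr_series()] of monthly rainfall.
#' @return list of [fr_raster()] annual totals, named by calendar year
#'   (years with complete 12-month coverage only).
#' @export
annual_rainfall <- function(series) {
  years <- unique(series$time$year)
  years <- years[vapply(years, function(y) sum(series$time$year == y) == 12L,
                        TRUE)]
  out <- lapply(years, function(y) {
    k <- which(series$time$year == y)
    fr_raster(apply(series$arr[, , k, drop = FALSE], c(1, 2), sum),
              series$xmin, series$ymin, series$pixel_size)
  })
  names(out) <- years
  out
}

#' Per-pixel trend in annual rainfall
#'
#' Gaussian GLM of annual total against year in every rainfall pixel,
#' returning the slope (mm/yr per year), the intercept at the first year,
#' and the mean annual rainfall. The slope is the closed-form least-squares
#' solution, applied to all pixels at once.
#'
#' @param series an [fr_series()] of monthly rainfall.
#' @return list of [fr_raster()]: `slope`, `intercept`, `mean_annual`,
#'   plus `years` used.
#' @export
annual_rainfall_trend <- function(series) {
  ann <- annual_rainfall(series)
  if (length(ann) < 3L) stop("need at least 3 complete years for a trend")
  years <- as.integer(names(ann))
  t <- years - years[1]
  Y <- vapply(ann, function(r) as.vector(r$values),
              numeric(length(ann[[1]]$values)))       # cells x years
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
  tbar <- mean(t)
  slope <- as.vector((Y %*% (t - tbar)) / sum((t - tbar)^2))
  ybar <- rowMeans(Y)
  intercept <- ybar - slope * tbar
  shape <- function(v) fr_raster(matrix(v, dim(series$arr)[1]),
                                 series$xmin, series$ymin, series$pixel_size)
  list(slope = shape(slope), intercept = shape(intercept),
       mean_annual = shape(ybar), years = years)
}

#' Extract a static surface value at a fire centroid
#'
#' Nearest-cell (containing-cell) lookup under the half-open convention;
#' categorical surfaces return their labels. Nodata at the centroid yields
#' a missing value with a warning.
#'
#' @param fire one row of the event table (needs `centroid_x`,
#'   `centroid_y`).
#' @param surface an [fr_raster()] (numeric or character values).
#' @return the cell value (NA if nodata).
#' @export
extract_static <- function(fire, surface) {
  v <- fr_value_at(surface, fire$centroid_x, fire$centroid_y)
  if (any(is.na(v)))
    warning("nodata at fire centroid; covariate set to missing")
  v
}

#' Assemble the per-fire covariate table
#'
#' One row per fire event: monthly and cumulative rainfall, static-surface
#' extractions, boma density (from the yearly predicted surfaces), the
#' three-month cumulative wildebeest utilization, and the management unit.
#' Any covariate whose input is not supplied is left out.
#'
#' @param events event table from [compute_characteristics()].
#' @param rain an [fr_series()] of monthly rainfall.
#' @param cumulative_mode window convention for [cumulative_rain_at()].
#' @param statics named list of [fr_raster()] static surfaces (e.g.
#'   `elevation`, `slope`, `soil`).
#' @param boma_by_year named list (by year) of predicted boma-density
#'   rasters from [predict_density()].
#' @param uds named list (`"YYYY-MM"`) of population utilization rasters
#'   for [utilization_3mo()].
#' @return data.frame keyed by `event_id`.
#' @export
build_fire_covariates <- function(events, rain = NULL,
                                  cumulative_mode = "prev_rainfall_year_start",
                                  statics = NULL, boma_by_year = NULL,
                                  uds = NULL) {
  out <- events[, c("event_id", "unit"), drop = FALSE]
  n <- nrow(events)
  if (!is.null(rain)) {
    out$monthly_rain <- vapply(seq_len(n), function(i)
      monthly_rain_at(events[i, ], rain), 0)
    # fires too early in the record lack the full cumulative window: missing
    out$cumulative_rain <- vapply(seq_len(n), function(i)
      tryCatch(cumulative_rain_at(events[i, ], rain, cumulative_mode),
               error = function(e) NA_real_), 0)
  }
  for (nm in names(statics)) {
    vals <- vapply(seq_len(n), function(i) {
      v <- fr_value_at(statics[[nm]], events$centroid_x[i],
                       events$centroid_y[i])
      as.character(v)
    }, "")
    num <- suppressWarnings(as.numeric(vals))
    out[[nm]] <- if (is.numeric(statics[[nm]]$values)) num else vals
  }
  if (!is.null(boma_by_year)) {
    out$boma_density <- vapply(seq_len(n), function(i) {
      r <- boma_by_year[[as.character(events$calendar_year[i])]]
      if (is.null(r)) return(NA_real_)
      fr_value_at(r, events$centroid_x[i], events$centroid_y[i])
    }, 0)
  }
  if (!is.null(uds)) {
    out$wildebeest_3mo <- vapply(seq_len(n), function(i)
      suppressWarnings(utilization_3mo(events[i, ], uds)), 0)
  }
  out
}
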
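#' Configuration for a synthetic savannah landscape
#'
#' Defines the grid, study years and management-unit structure every
#' generator works on. Defaults emulate a 500 m burned-area grid observed
#' over 2001-2014.
#'
#' @param grid_nrows,grid_ncols pixel counts (> 0).
#' @param pixel_size_m pixel edge, metres (default 500).
#' @param origin_xy lower-left corner in map units.
#' @param years inclusive calendar-year range (default 2001:2014).
#' @param seed integer RNG seed.
#' @param buffer_pixels width of the buffer strip, in pixels.
#' @return a `landscape_config` list with the grid geometry and a unit list
#'   from [make_management_units()].
#' @export
landscape_config <- function(grid_nrows = 50L, grid_ncols = 50L,
                             pixel_size_m = 500, origin_xy = c(0, 0),
                             years = 2001:2014, seed = 1L,
                             buffer_pixels = 4L) {
  if (grid_nrows <= 0 || grid_ncols <= 0) stop("grid dimensions must be > 0")
  if (pixel_size_m <= 0) stop("pixel_size_m must be > 0")
  if (length(years) == 0) stop("year range must be non-empty")
  width <- grid_ncols * pixel_size_m
  height <- grid_nrows * pixel_size_m
  cfg <- list(
    grid_nrows = as.integer(grid_nrows),
    grid_ncols = as.integer(grid_ncols),
    pixel_size_m = pixel_size_m,
    xmin = origin_xy[1], ymin = origin_xy[2],
    width_m = width, height_m = height,
    years = as.integer(years), seed = as.integer(seed),
    units = make_management_units(width, height, buffer_pixels * pixel_size_m)
  )
  class(cfg) <- "landscape_config"
  cfg
}

# blank raster on the landscape grid
cfg_raster <- function(cfg, fill = NA_real_) {
  fr_raster(
    matrix(fill, cfg$grid_nrows, cfg$grid_ncols),
    xmin = cfg$xmin, ymin = cfg$ymin, pixel_size = cfg$pixel_size_m
  )
}

# neighbour offsets for 4- or 8-connectivity
conn_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8L) {
    cbind(dr = rep(-1:1, each = 3L), dc = rep(-1:1, 3L))[-5L, , drop = FALSE]
  } else stop("connectivity must be 4 or 8")
}

#' Generate a multi-year burn history with known fire labels
#'
#' Fires are grown by stochastic dilation from a random seed pixel; each
#' pixel's burn date is the ignition date plus its hop count from the seed,
#' capped at 5 days, so every fire satisfies the <= 5-day intra-fire date
#' span by construction. Distinct fires of a year are kept spatially
#' non-adjacent (a one-pixel moat) and ignition days stay within day-of-year
#' 15-340, so fires of different years are always more than 5 days apart:
#' the ground-truth labels are exactly recoverable by the flood-fill
#' clustering contract. Fire sizes are drawn from a truncated log-normal
#' around `mean_fire_pixels`; ignition days follow the two dry seasons.
#'
#' @param cfg a [landscape_config()].
#' @param n_fires_per_year fires per study year (>= 0).
#' @param mean_fire_pixels mean fire size, pixels (>= 1).
#' @param size_sdlog log-scale spread of the fire-size distribution.
#' @return list with `records` (data.frame `year`, `row`, `col`,
#'   `burn_date` in days since 2000-01-01, `true_event` label), `stack`
#'   (per-year list of [fr_raster()] burn-date grids) and `truth` (the
#'   ground-truth parameter list).
#' @export
generate_burn_history <- function(cfg, n_fires_per_year, mean_fire_pixels,
                                  size_sdlog = 0.7) {
  stopifnot(n_fires_per_year >= 0, mean_fire_pixels >= 1)
  set.seed(cfg$seed)
  nr <- cfg$grid_nrows; nc <- cfg$grid_ncols
  ncells <- nr * nc
  if (n_fires_per_year * mean_fire_pixels * 4 > ncells) {
    stop(sprintf(
      "capacity: %d fires of ~%d pixels (plus separation moats) exceed a %d-cell grid",
      n_fires_per_year, mean_fire_pixels, ncells
    ))
  }
  offs <- conn_offsets(4L)      # growth by edge adjacency; clustering uses 8
  recs <- vector("list", length(cfg$years) * max(n_fires_per_year, 1L))
  event_id <- 0L
  meanlog <- log(mean_fire_pixels) - size_sdlog^2 / 2
  for (year in cfg$years) {
    blocked <- matrix(FALSE, nr, nc)
    if (n_fires_per_year == 0) next
    for (f in seq_len(n_fires_per_year)) {
      target <- 0L
      while (target < 1L || target > ncells %/% 4L)
        target <- as.integer(round(stats::rlnorm(1, meanlog, size_sdlog)))
      placed <- FALSE
      for (try in 1:200) {
        seed_cell <- sample.int(ncells, 1L)
        sr <- (seed_cell - 1L) %% nr + 1L
        sc <- (seed_cell - 1L) %/% nr + 1L
        if (blocked[sr, sc]) next
        # grow the patch
        in_patch <- matrix(FALSE, nr, nc)
        in_patch[sr, sc] <- TRUE
        cells <- matrix(c(sr, sc), 1L, 2L)
        hops <- 0L
        while (nrow(cells) < target) {
          frontier <- NULL
          for (k in seq_len(nrow(offs))) {
            rr <- cells[, 1] + offs[k, 1]; cc <- cells[, 2] + offs[k, 2]
            ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
            rr <- rr[ok]; cc <- cc[ok]
            free <- !in_patch[cbind(rr, cc)] & !blocked[cbind(rr, cc)]
            if (any(free)) {
              frontier <- rbind(frontier,
                                cbind(rr[free], cc[free], hops[ok][free] + 1L))
            }
          }
          if (is.null(frontier) || nrow(frontier) == 0L) break
          pick <- frontier[sample.int(nrow(frontier), 1L), ]
          if (in_patch[pick[1], pick[2]]) next
          in_patch[pick[1], pick[2]] <- TRUE
          cells <- rbind(cells, pick[1:2])
          hops <- c(hops, pick[3])
        }
        if (nrow(cells) >= 1L) {
          # day-of-year from the two dry seasons (long dry Jun-Sep, short Jan-Feb)
          doy <- if (stats::runif(1) < 0.65) sample(170:270, 1L)
                 else sample(15:60, 1L)
          ign <- day_from_date(as.Date(sprintf("%d-01-01", year))) + doy
          event_id <- event_id + 1L
          recs[[event_id]] <- data.frame(
            year = year, row = cells[, 1], col = cells[, 2],
            burn_date = ign + pmin(hops, 5L), true_event = event_id
          )
          # moat: block the patch and its 8-neighbourhood for this year
          for (dr in -1:1) for (dc in -1:1) {
            rr <- pmin(pmax(cells[, 1] + dr, 1L), nr)
            cc <- pmin(pmax(cells[, 2] + dc, 1L), nc)
            blocked[cbind(rr, cc)] <- TRUE
          }
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(
          "capacity: could not place fire %d of year %d on the %dx%d grid",
          f, year, nr, nc
        ))
      }
    }
  }
  records <- if (event_id > 0L) do.call(rbind, recs[seq_len(event_id)])
             else data.frame(year = integer(), row = integer(),
                             col = integer(), burn_date = integer(),
                             true_event = integer())
  rownames(records) <- NULL
  stack <- lapply(cfg$years, function(y) {
    r <- cfg_raster(cfg)
    sub <- records[records$year == y, , drop = FALSE]
    r$values[cbind(sub$row, sub$col)] <- sub$burn_date
    r
  })
  names(stack) <- cfg$years
  truth <- list(
    labels = records,
    n_fires_per_year = n_fires_per_year,
    mean_fire_pixels = mean_fire_pixels,
    size_sdlog = size_sdlog
  )
  list(records = records, stack = stack, truth = truth)
}

#' Generate active-fire detections over a known burn history
#'
#' Emulates a thermal-anomaly point product: each true fire is observed at
#' satellite overpass with probability `detection_prob`; a detected fire
#' yields one or more detections at random pixels of its footprint, dated by
#' the pixel burn date, with fire radiative power drawn from a log-normal
#' distribution (`meanlog = log(frp_scale)`, `sdlog = frp_sdlog`; parameters
#' recorded in the attributes).
#'
#' @param burns output of [generate_burn_history()].
#' @param cfg the [landscape_config()] used to generate `burns`.
#' @param detection_prob per-fire detection probability in `[0, 1]`.
#' @param frp_scale median FRP, MW/km^2.
#' @param frp_sdlog log-scale FRP spread.
#' @return data.frame with `x`, `y`, `date`, `frp`; attributes record the
#'   FRP distribution parameters.
#' @export
generate_active_fires <- function(burns, cfg, detection_prob,
                                  frp_scale = 10, frp_sdlog = 1) {
  if (detection_prob < 0 || detection_prob > 1)
    stop("detection_prob must be in [0, 1]")
  set.seed(cfg$seed + 1L)
  tmpl <- cfg_raster(cfg)
  recs <- burns$records
  out <- list()
  for (ev in unique(recs$true_event)) {
    if (stats::runif(1) > detection_prob) next
    sub <- recs[recs$true_event == ev, , drop = FALSE]
    n_det <- 1L + stats::rpois(1, 0.8)
    pick <- sample.int(nrow(sub), min(n_det, nrow(sub)))
    ctr <- fr_cell_center(tmpl, sub$row[pick], sub$col[pick])
    jit <- cfg$pixel_size_m * 0.4
    out[[length(out) + 1L]] <- data.frame(
      x = ctr$x + stats::runif(length(pick), -jit, jit),
      y = ctr$y + stats::runif(length(pick), -jit, jit),
      date = sub$burn_date[pick],
      frp = stats::rlnorm(length(pick), log(frp_scale), frp_sdlog)
    )
  }
  det <- if (length(out)) do.call(rbind, out)
         else data.frame(x = numeric(), y = numeric(),
                         date = integer(), frp = numeric())
  attr(det, "frp_meanlog") <- log(frp_scale)
  attr(det, "frp_sdlog") <- frp_sdlog
  attr(det, "detection_prob") <- detection_prob
  det
}

# circular-calendar monthly rainfall weights: wet peaks in April (long rains)
# and November (short rains), dry troughs in July-August and February
.RAIN_MONTH_W <- c(0.09, 0.07, 0.11, 0.13, 0.10, 0.03,
                   0.02, 0.02, 0.04, 0.10, 0.15, 0.14)

#' Generate a bimodal monthly rainfall series
#'
#' Mean annual rainfall declines linearly from west to east (the
#' `west_east_gradient`, mm/yr per km of easting; negative for the usual
#' wet-west pattern) with an optional linear annual trend. Months follow a
#' fixed bimodal seasonal profile (peaks in the Mar-May long rains and the
#' Oct-Dec short rains) with multiplicative mean-one log-normal noise, so
#' expected annual totals remain exactly linear in year.
#'
#' @param cfg a [landscape_config()].
#' @param west_east_gradient mm/yr per km of easting.
#' @param trend mm/yr per year.
#' @param base_annual mm/yr at the western edge in the first study year.
#' @param rain_pixel_factor rainfall pixels are this many landscape pixels
#'   across (a coarser climate grid, as for satellite rainfall products).
#' @param noise_sdlog log-scale monthly noise (0 for a deterministic field).
#' @return an [fr_series()] of monthly rainfall, mm/month; the gradient and
#'   trend are recorded in the attributes.
#' @export
generate_rainfall <- function(cfg, west_east_gradient = -8, trend = 0,
                              base_annual = 900, rain_pixel_factor = 10,
                              noise_sdlog = 0.1) {
  set.seed(cfg$seed + 2L)
  px <- cfg$pixel_size_m * rain_pixel_factor
  nr <- as.integer(ceiling(cfg$height_m / px))
  nc <- as.integer(ceiling(cfg$width_m / px))
  time <- month_seq(cfg$years[1], 1L, cfg$years[length(cfg$years)], 12L)
  arr <- array(NA_real_, c(nr, nc, nrow(time)))
  east_km <- (matrix(rep(seq_len(nc), each = nr), nr, nc) - 0.5) * px / 1000
  w <- .RAIN_MONTH_W / sum(.RAIN_MONTH_W)
  for (k in seq_len(nrow(time))) {
    yr <- time$year[k]; mo <- time$month[k]
    annual <- pmax(base_annual + west_east_gradient * east_km +
                     trend * (yr - cfg$years[1]), 50)
    noise <- if (noise_sdlog > 0) {
      exp(stats::rnorm(nr * nc, -noise_sdlog^2 / 2, noise_sdlog))
    } else 1
    arr[, , k] <- annual * w[mo] * noise
  }
  s <- fr_series(arr, time, xmin = cfg$xmin, ymin = cfg$ymin, pixel_size = px)
  attr(s, "west_east_gradient") <- west_east_gradient
  attr(s, "trend") <- trend
  attr(s, "base_annual") <- base_annual
  s
}

#' Generate boma-count observations in overlapping image footprints
#'
#' Rectangular image-overlap footprints are scattered over the landscape;
#' within each, yearly counts are Poisson draws around
#' `density(year) * area`, with `density(year) = max(0, base + slope *
#' (year - first year))`. Baseline densities reflect management: highest in
#' the buffer, intermediate where livestock are permitted, near zero in
#' exclusion units.
#'
#' @param cfg a [landscape_config()].
#' @param slope rate of change of boma density, bomas km^-2 yr^-1 (a single
#'   number applied everywhere, or a `function(x, y)` field).
#' @param n_footprints number of footprints.
#' @param obs_years candidate observation years.
#' @param base_density named vector with elements `buffer`, `permitted`,
#'   `excluded` (bomas/km^2).
#' @param years_per_footprint range of distinct observation years drawn per
#'   footprint; a small share of footprints gets a single year (these
#'   contribute baseline information only downstream).
#' @return data.frame with one row per footprint-year: `footprint_id`,
#'   `year`, `count`, `area_km2`, footprint bounds, centroid and `unit`;
#'   the truth (per-footprint base and slope) is attached as an attribute.
#' @export
generate_boma_observations <- function(cfg, slope = 0.05, n_footprints = 60L,
                                       obs_years = NULL,
                                       base_density = c(buffer = 2, permitted = 1,
                                                        excluded = 0.15),
                                       years_per_footprint = c(2L, 5L)) {
  set.seed(cfg$seed + 3L)
  if (is.null(obs_years)) obs_years <- cfg$years
  slope_fun <- if (is.function(slope)) slope else function(x, y) slope
  rows <- list()
  truth <- list()
  for (fp in seq_len(n_footprints)) {
    w <- stats::runif(1, 0.08, 0.2) * cfg$width_m
    h <- stats::runif(1, 0.08, 0.2) * cfg$height_m
    if (w * h < 1e4) stop("footprint of area 0 rejected")
    # footprints may extend past the landscape edge (as satellite images
    # do); clip, so the narrow buffer strip is sampled too
    x0r <- stats::runif(1, -w / 2, cfg$width_m - w / 2) + cfg$xmin
    y0r <- stats::runif(1, -h / 2, cfg$height_m - h / 2) + cfg$ymin
    x0 <- max(cfg$xmin, x0r); x1 <- min(cfg$xmin + cfg$width_m, x0r + w)
    y0 <- max(cfg$ymin, y0r); y1 <- min(cfg$ymin + cfg$height_m, y0r + h)
    w <- x1 - x0; h <- y1 - y0
    cx <- x0 + w / 2; cy <- y0 + h / 2
    area <- w * h / 1e6
    unit <- assign_unit(cx, cy, cfg$units)
    u <- cfg$units[[unit]]
    base <- if (u$is_buffer) base_density[["buffer"]]
            else if (u$livestock_permitted) base_density[["permitted"]]
            else base_density[["excluded"]]
    sl <- slope_fun(cx, cy)
    n_years <- if (fp %% 10L == 0L) 1L
               else sample(seq(years_per_footprint[1], years_per_footprint[2]), 1L)
    yrs <- sort(sample(obs_years, min(n_years, length(obs_years))))
    dens <- pmax(0, base + sl * (yrs - cfg$years[1]))
    rows[[fp]] <- data.frame(
      footprint_id = fp, year = yrs,
      count = stats::rpois(length(yrs), dens * area),
      area_km2 = area, xmin = x0, xmax = x0 + w, ymin = y0, ymax = y0 + h,
      cx = cx, cy = cy, unit = unit
    )
    truth[[fp]] <- data.frame(footprint_id = fp, base = base, slope = sl,
                              unit = unit)
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  attr(obs, "truth") <- do.call(rbind, truth)
  obs
}

#' Simulate GPS trajectories of collared animals
#'
#' Pure Brownian-motion walkers with known motion variance, observed at a
#' fixed interval with Gaussian location error; per-month fix counts may be
#' deliberately unbalanced to exercise the Voronoi reweighting rule.
#'
#' @param cfg a [landscape_config()].
#' @param n_individuals number of walkers (>= 1).
#' @param months data.frame with columns `year`, `month` (defaults to the
#'   first four study months).
#' @param fix_interval_hours hours between fixes.
#' @param sigma2_m Brownian motion variance, m^2/s.
#' @param loc_error_sd GPS location error SD, metres.
#' @param fixes_per_month optional integer vector (one per month) overriding
#'   the number of fixes retained per month, to create unbalanced sampling.
#' @return data.frame `id`, `t` (seconds from the study epoch), `x`, `y`,
#'   `year`, `month`; the true `sigma2_m` and `loc_error_sd` are attached as
#'   attributes.
#' @export
generate_trajectories <- function(cfg, n_individuals = 3L, months = NULL,
                                  fix_interval_hours = 3, sigma2_m = 50,
                                  loc_error_sd = 20,
                                  fixes_per_month = NULL) {
  stopifnot(n_individuals >= 1)
  set.seed(cfg$seed + 4L)
  if (is.null(months))
    months <- data.frame(year = cfg$years[1], month = 1:4)
  dt <- fix_interval_hours * 3600
  out <- list()
  for (id in seq_len(n_individuals)) {
    x <- cfg$xmin + cfg$width_m * stats::runif(1, 0.35, 0.65)
    y <- cfg$ymin + cfg$height_m * stats::runif(1, 0.35, 0.65)
    for (mi in seq_len(nrow(months))) {
      first <- as.Date(sprintf("%d-%02d-01", months$year[mi], months$month[mi]))
      n_days <- as.integer(seq(first, by = "1 month", length.out = 2)[2] - first)
      n_fix <- as.integer(n_days * 24 / fix_interval_hours)
      sd_step <- sqrt(sigma2_m * dt)
      xs <- x + cumsum(c(0, stats::rnorm(n_fix - 1L, 0, sd_step)))
      ys <- y + cumsum(c(0, stats::rnorm(n_fix - 1L, 0, sd_step)))
      x <- xs[n_fix]; y <- ys[n_fix]
      keep <- seq_len(n_fix)
      if (!is.null(fixes_per_month)) {
        k <- fixes_per_month[mi]
        keep <- sort(sample.int(n_fix, min(k, n_fix)))
      }
      t0 <- as.numeric(difftime(as.POSIXct(first, tz = "UTC"),
                                as.POSIXct(.FR_EPOCH, tz = "UTC"),
                                units = "secs"))
      out[[length(out) + 1L]] <- data.frame(
        id = id, t = t0 + (keep - 1L) * dt,
        x = xs[keep] + stats::rnorm(length(keep), 0, loc_error_sd),
        y = ys[keep] + stats::rnorm(length(keep), 0, loc_error_sd),
        year = months$year[mi], month = months$month[mi]
      )
    }
  }
  traj <- do.call(rbind, out)
  rownames(traj) <- NULL
  attr(traj, "sigma2_m") <- sigma2_m
  attr(traj, "loc_error_sd") <- loc_error_sd
  traj
}
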
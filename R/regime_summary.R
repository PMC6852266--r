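med <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else stats::median(x)
}

#' Annual fire-regime series
#'
#' Yearly totals and medians over events: number of fires, area burnt,
#' median fire size, median size of the largest decile, median ignition day,
#' median time since last fire, median radiative power, and the top-decile
#' share of burnt area. Characteristics with missing values (time since last
#' fire, radiative power) are excluded from their medians; years without
#' events get zero counts and missing medians.
#'
#' @param events event table from [compute_characteristics()].
#' @param years years to tabulate (default: range present in the events).
#' @return data.frame with one row per year.
#' @export
annual_series <- function(events, years = NULL) {
  if (is.null(years))
    years <- seq(min(events$calendar_year), max(events$calendar_year))
  rows <- lapply(years, function(y) {
    ev <- events[events$calendar_year == y, , drop = FALSE]
    n <- nrow(ev)
    top_sizes <- if (n > 0) {
      k <- ceiling(n / 10)
      ord <- order(-ev$size_km2, ev$event_id)
      ev$size_km2[ord][seq_len(k)]
    } else numeric(0)
    data.frame(
      year = y, n_fires = n,
      area_burnt_km2 = if (n > 0) sum(ev$size_km2) else 0,
      median_size_km2 = med(ev$size_km2),
      median_size_top_decile = med(top_sizes),
      median_ignition_day = med(ev$day_of_year),
      median_tslf_years = med(ev$tslf_years),
      median_frp = med(ev$frp_max),
      top_decile_share = if (n > 0) top_decile_share(ev) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Share of burnt area in the largest decile of fires
#'
#' Fraction of a year's burnt area contributed by its largest
#' `ceiling(n/10)` fires (ties broken by event id).
#'
#' @param events event table (>= 1 row), typically one year's fires.
#' @return fraction in (0, 1].
#' @export
top_decile_share <- function(events) {
  n <- nrow(events)
  if (n < 1L) stop("need at least one event")
  k <- ceiling(n / 10)
  ord <- order(-events$size_km2, events$event_id)
  sum(events$size_km2[ord][seq_len(k)]) / sum(events$size_km2)
}

#' Per-management-unit fire summaries
#'
#' Events are assigned to units by centroid and burnt pixels by location.
#' For each unit: total fires, median annual burnt area, and the median
#' annual proportion of the unit's area burnt, plus medians of the fire
#' characteristics (all fires and largest-decile fires, since either may be
#' wanted).
#'
#' @param events event table.
#' @param records clustered burn records (for pixel-level area assignment).
#' @param cfg the [landscape_config()].
#' @return data.frame with one row per unit.
#' @export
unit_summary <- function(events, records, cfg) {
  units <- cfg$units
  check_units_disjoint(units)
  areas <- unit_areas_km2(units)
  tmpl <- cfg_raster(cfg)
  px_km2 <- (cfg$pixel_size_m / 1000)^2
  ctr <- fr_cell_center(tmpl, records$row, records$col)
  rec_unit <- assign_unit(ctr$x, ctr$y, units)
  rec_year <- calendar_year_of(records$burn_date)
  years <- sort(unique(rec_year))
  rows <- lapply(names(units), function(nm) {
    ev <- events[!is.na(events$unit) & events$unit == nm, , drop = FALSE]
    # yearly burnt area inside the unit, zero-filled
    yearly <- vapply(years, function(y)
      sum(rec_unit == nm & rec_year == y, na.rm = TRUE) * px_km2, 0)
    top <- if (nrow(ev) > 0) {
      k <- ceiling(nrow(ev) / 10)
      ord <- order(-ev$size_km2, ev$event_id)
      ev[ord[seq_len(k)], , drop = FALSE]
    } else ev
    data.frame(
      unit = nm, area_km2 = areas[[nm]],
      n_fires = nrow(ev),
      median_annual_burnt_km2 = med(yearly),
      proportion_burnt = med(yearly) / areas[[nm]],
      median_size_km2 = med(ev$size_km2),
      median_size_top_decile = med(top$size_km2),
      median_ignition_day = med(ev$day_of_year),
      median_tslf_years = med(ev$tslf_years),
      median_frp = med(ev$frp_max)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

check_units_disjoint <- function(units) {
  prot <- units[!vapply(units, `[[`, TRUE, "is_buffer")]
  if (length(prot) < 2L) return(invisible(TRUE))
  for (i in seq_along(prot)) {
    for (j in seq_along(prot)) {
      if (i >= j) next
      ri <- prot[[i]]$ring; rj <- prot[[j]]$ring
      ci <- c(mean(range(ri[, 1])), mean(range(ri[, 2])))
      cj <- c(mean(range(rj[, 1])), mean(range(rj[, 2])))
      if (point_in_polygon(ci[1], ci[2], rj) ||
          point_in_polygon(cj[1], cj[2], ri))
        stop(sprintf("management units %s and %s overlap",
                     prot[[i]]$name, prot[[j]]$name))
    }
  }
  invisible(TRUE)
}

#' Coarse-grid template over the landscape
#'
#' A raster of `cell_km` x `cell_km` cells covering the landscape extent
#' (the final row/column is padded when the cell size does not divide the
#' extent).
#'
#' @param cfg the [landscape_config()].
#' @param cell_km cell edge, km (default 6).
#' @return an [fr_raster()] of NA values.
#' @export
coarse_grid <- function(cfg, cell_km = 6) {
  px <- cell_km * 1000
  nr <- as.integer(ceiling(cfg$height_m / px))
  nc <- as.integer(ceiling(cfg$width_m / px))
  fr_raster(matrix(NA_real_, nr, nc), cfg$xmin, cfg$ymin, px)
}

#' Rasterize yearly fire characteristics to a coarse grid
#'
#' Per cell and year: burnt area (the summed area of burnt pixels whose
#' centres fall in the cell, so a fire straddling cells is split and area is
#' conserved), number of fires (event centroids, so each fire counts once),
#' and medians of size, ignition day, time since last fire and radiative
#' power over the events whose centroid falls in the cell.
#'
#' @param events event table.
#' @param records clustered burn records.
#' @param cfg the [landscape_config()].
#' @param cell_km coarse cell edge, km.
#' @return list of yearly raster stacks: each element (`area_burnt`,
#'   `n_fires`, `median_size`, `median_ignition`, `median_tslf`,
#'   `median_frp`) is a list of [fr_raster()] named by year.
#' @export
rasterize_characteristic <- function(events, records, cfg, cell_km = 6) {
  grid <- coarse_grid(cfg, cell_km)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  tmpl <- cfg_raster(cfg)
  px_km2 <- (cfg$pixel_size_m / 1000)^2
  rec_ctr <- fr_cell_center(tmpl, records$row, records$col)
  rec_cell <- fr_cell_at(grid, rec_ctr$x, rec_ctr$y)
  rec_year <- calendar_year_of(records$burn_date)
  ev_cell <- fr_cell_at(grid, events$centroid_x, events$centroid_y)
  years <- sort(unique(c(rec_year, events$calendar_year)))
  blank <- function() matrix(NA_real_, nr, nc)
  out <- list(area_burnt = list(), n_fires = list(), median_size = list(),
              median_ignition = list(), median_tslf = list(),
              median_frp = list())
  for (y in years) {
    area <- matrix(0, nr, nc)
    sel <- rec_year == y
    if (any(sel)) {
      tab <- table(rec_cell$row[sel], rec_cell$col[sel])
      area[cbind(as.integer(rownames(tab))[row(tab)],
                 as.integer(colnames(tab))[col(tab)])] <-
        as.vector(tab) * px_km2
    }
    nf <- matrix(0, nr, nc)
    ms <- blank(); mi <- blank(); mt <- blank(); mf <- blank()
    esel <- which(events$calendar_year == y)
    if (length(esel)) {
      cell_id <- (ev_cell$col[esel] - 1L) * nr + ev_cell$row[esel]
      for (cid in unique(cell_id)) {
        ii <- esel[cell_id == cid]
        r <- (cid - 1L) %% nr + 1L; cc <- (cid - 1L) %/% nr + 1L
        nf[r, cc] <- length(ii)
        ms[r, cc] <- med(events$size_km2[ii])
        mi[r, cc] <- med(events$day_of_year[ii])
        mt[r, cc] <- med(events$tslf_years[ii])
        mf[r, cc] <- med(events$frp_max[ii])
      }
    }
    wrap <- function(m) fr_raster(m, grid$xmin, grid$ymin, grid$pixel_size)
    ylab <- as.character(y)
    out$area_burnt[[ylab]] <- wrap(area)
    out$n_fires[[ylab]] <- wrap(nf)
    out$median_size[[ylab]] <- wrap(ms)
    out$median_ignition[[ylab]] <- wrap(mi)
    out$median_tslf[[ylab]] <- wrap(mt)
    out$median_frp[[ylab]] <- wrap(mf)
  }
  out
}

#' Area never burnt over the study period
#'
#' @param records burn records covering the full study period.
#' @param cfg the [landscape_config()].
#' @return list with `km2` and `fraction` of the study area that has no
#'   burn record in any year.
#' @export
unburnt_extent <- function(records, cfg) {
  total <- cfg$grid_nrows * cfg$grid_ncols
  burned <- nrow(unique(records[, c("row", "col")]))
  px_km2 <- (cfg$pixel_size_m / 1000)^2
  list(km2 = (total - burned) * px_km2, fraction = (total - burned) / total)
}
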
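#' Delineate fire events by spatio-temporal flood fill
#'
#' Partitions burned-pixel records into individual fires: two records belong
#' to the same event iff they are connected by a chain of spatially adjacent
#' record pairs each differing by at most `max_gap_days` in burn date (the
#' transitive closure, computed by union-find). Because the rule is applied
#' pairwise along chains, an event's total date span may exceed
#' `max_gap_days`. Records at the same pixel (repeat burns) are spatially
#' adjacent to each other; repeat burns further apart in time than the gap
#' fall into different events.
#'
#' Event ids are assigned deterministically: events are numbered by ignition
#' date, then by the row, then the column of their first-burning pixel.
#'
#' @param records data.frame with integer columns `row`, `col`, `burn_date`
#'   (days since 2000-01-01); rows must be unique on (row, col, burn_date).
#' @param max_gap_days maximum date difference between adjacent pixels of
#'   one fire (days, >= 0; default 5).
#' @param connectivity spatial adjacency, 4 or 8 neighbours (default 8).
#' @return `records` with an integer `event_id` column appended.
#' @export
cluster_burned_pixels <- function(records, max_gap_days = 5L,
                                  connectivity = 8L) {
  stopifnot(max_gap_days >= 0)
  n <- nrow(records)
  if (n == 0L) {
    records$event_id <- integer(0)
    return(records)
  }
  key3 <- paste(records$row, records$col, records$burn_date)
  if (anyDuplicated(key3)) {
    d <- key3[duplicated(key3)][1]
    stop(sprintf("duplicate record at (row, col, burn_date) = (%s)",
                 gsub(" ", ", ", d)))
  }
  offs <- rbind(c(0L, 0L), conn_offsets(connectivity))
  # union-find with path halving
  parent <- seq_len(n)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # integer pixel ids so neighbour lookup is a vectorized match, not a scan
  key_mult <- max(records$col) - min(records$col) + 3L
  pixid <- (records$row - min(records$row)) * key_mult +
    (records$col - min(records$col))
  upix <- sort(unique(pixid))
  by_pix <- split(seq_len(n), match(pixid, upix))
  for (k in seq_len(nrow(offs))) {
    nb_id <- pixid + offs[k, 1] * key_mult + offs[k, 2]
    nb_slot <- match(nb_id, upix)
    for (i in which(!is.na(nb_slot))) {
      for (j in by_pix[[nb_slot[i]]]) {
        if (j <= i) next
        if (abs(records$burn_date[i] - records$burn_date[j]) <= max_gap_days) {
          ri <- uf_find(i); rj <- uf_find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  root <- vapply(seq_len(n), uf_find, 0L)
  # deterministic event numbering: ignition date, then row, then col of the
  # lexicographically first record at the ignition date
  grp <- match(root, unique(root))
  ord_rec <- order(records$burn_date, records$row, records$col)
  first_of <- ord_rec[!duplicated(grp[ord_rec])]
  rank <- order(order(records$burn_date[first_of], records$row[first_of],
                      records$col[first_of]))
  names(rank) <- grp[first_of]
  records$event_id <- as.integer(rank[as.character(grp)])
  records
}

#' Compute per-fire characteristics
#'
#' For each delineated event: size in pixels and km^2, centroid, ignition
#' date (the earliest burn date), calendar year, rainfall year, zero-based
#' day of year, and mean time since last fire. The last is the mean, over
#' the event's pixels that burned at least once before the ignition date, of
#' `(ignition_date - most recent prior burn) / 365.25` years; it is missing
#' when no pixel of the event burned before (common early in a study
#' period).
#'
#' @param clustered output of [cluster_burned_pixels()] (records with
#'   `event_id`).
#' @param cfg the [landscape_config()] describing the grid (used for pixel
#'   size and centroid coordinates).
#' @param history optional data.frame of burn records (`row`, `col`,
#'   `burn_date`) to search for prior burns; defaults to `clustered` itself,
#'   i.e. the full record set under analysis.
#' @return data.frame with one row per event: `event_id`, `size_pixels`,
#'   `size_km2`, `centroid_x`, `centroid_y`, `ignition_date`,
#'   `calendar_year`, `rainfall_year`, `day_of_year`, `tslf_years`,
#'   `frp_max` (NA until [attach_frp()]), and the event's management `unit`.
#' @export
compute_characteristics <- function(clustered, cfg, history = NULL) {
  if (nrow(clustered) == 0L) stop("empty record set: no events to summarize")
  if (is.null(history)) history <- clustered
  px_km2 <- (cfg$pixel_size_m / 1000)^2
  tmpl <- cfg_raster(cfg)
  hist_by_pix <- split(history$burn_date, paste(history$row, history$col))
  events <- split(seq_len(nrow(clustered)), clustered$event_id)
  out <- lapply(names(events), function(id) {
    idx <- events[[id]]
    rows <- clustered$row[idx]; cols <- clustered$col[idx]
    dates <- clustered$burn_date[idx]
    ign <- min(dates)
    ctr <- fr_cell_center(tmpl, rows, cols)
    # time since last fire: most recent prior burn per pixel
    tslf_pix <- vapply(seq_along(idx), function(i) {
      prior <- hist_by_pix[[paste(rows[i], cols[i])]]
      prior <- prior[prior < ign]
      if (length(prior) == 0L) NA_real_ else (ign - max(prior)) / 365.25
    }, 0)
    data.frame(
      event_id = as.integer(id),
      size_pixels = length(idx),
      size_km2 = length(idx) * px_km2,
      centroid_x = mean(ctr$x), centroid_y = mean(ctr$y),
      ignition_date = ign,
      calendar_year = calendar_year_of(ign),
      rainfall_year = rainfall_year(ign),
      day_of_year = day_of_year0(ign),
      tslf_years = if (all(is.na(tslf_pix))) NA_real_
                   else mean(tslf_pix, na.rm = TRUE),
      frp_max = NA_real_
    )
  })
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$event_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev$unit <- assign_unit(ev$centroid_x, ev$centroid_y, cfg$units)
  ev
}

#' Attach maximum fire radiative power to events
#'
#' An active-fire detection matches an event when it falls on a pixel of the
#' event's footprint and is dated within the event's burn-date span padded
#' by `date_tolerance_days` (overpass timing and composite dating are offset
#' by up to a day). An event's intensity is the maximum radiative power over
#' its matching detections; events with none keep a missing value.
#'
#' @param events output of [compute_characteristics()].
#' @param clustered the clustered records the events were built from.
#' @param detections data.frame `x`, `y`, `date`, `frp` (MW/km^2, as given
#'   by the input product; `frp` must be >= 0).
#' @param cfg the [landscape_config()] describing the grid.
#' @param date_tolerance_days temporal padding, days (default 1).
#' @return `events` with `frp_max` filled in where detections match.
#' @export
attach_frp <- function(events, clustered, detections, cfg,
                       date_tolerance_days = 1L) {
  if (nrow(detections) == 0L) return(events)
  if (any(detections$frp < 0)) stop("frp must be >= 0")
  tmpl <- cfg_raster(cfg)
  cells <- fr_cell_at(tmpl, detections$x, detections$y)
  rec_key <- paste(clustered$row, clustered$col)
  span <- do.call(rbind, lapply(split(clustered$burn_date, clustered$event_id),
                                range))
  ev_of_rec <- split(clustered$event_id, rec_key)
  frp_best <- rep(NA_real_, nrow(events))
  names(frp_best) <- events$event_id
  for (i in seq_len(nrow(detections))) {
    cand <- unique(ev_of_rec[[paste(cells$row[i], cells$col[i])]])
    if (is.null(cand)) next
    for (ev in cand) {
      lo <- span[as.character(ev), 1] - date_tolerance_days
      hi <- span[as.character(ev), 2] + date_tolerance_days
      if (detections$date[i] >= lo && detections$date[i] <= hi) {
        k <- as.character(ev)
        if (is.na(frp_best[k]) || detections$frp[i] > frp_best[k])
          frp_best[k] <- detections$frp[i]
      }
    }
  }
  events$frp_max <- unname(frp_best[as.character(events$event_id)])
  events
}

#' Delineate fires and derive all characteristics in one call
#'
#' Convenience wrapper: [cluster_burned_pixels()] then
#' [compute_characteristics()] and, if detections are supplied,
#' [attach_frp()].
#'
#' @inheritParams cluster_burned_pixels
#' @inheritParams attach_frp
#' @param cfg the [landscape_config()].
#' @return list with `events` (the characteristics table) and `records`
#'   (records with `event_id`).
#' @export
delineate_fires <- function(records, cfg, detections = NULL,
                            max_gap_days = 5L, connectivity = 8L,
                            date_tolerance_days = 1L) {
  clustered <- cluster_burned_pixels(records, max_gap_days, connectivity)
  events <- compute_characteristics(clustered, cfg)
  if (!is.null(detections) && nrow(detections) > 0L)
    events <- attach_frp(events, clustered, detections, cfg,
                         date_tolerance_days)
  list(events = events, records = clustered)
}
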
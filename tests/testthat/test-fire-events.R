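test_that("a single burned pixel is one event of 0.25 km2", {
  cfg <- tiny_cfg(5L, 5L)
  rec <- data.frame(row = 2L, col = 3L, burn_date = 100L)
  cl <- cluster_burned_pixels(rec)
  expect_identical(cl$event_id, 1L)
  ev <- compute_characteristics(cl, cfg)
  expect_identical(ev$size_pixels, 1L)
  expect_equal(ev$size_km2, 0.25)
})

test_that("the temporal gap threshold splits at 6 days and merges at 5", {
  merge5 <- cluster_burned_pixels(
    data.frame(row = c(1L, 1L), col = c(1L, 2L), burn_date = c(10L, 15L))
  )
  expect_identical(length(unique(merge5$event_id)), 1L)
  split6 <- cluster_burned_pixels(
    data.frame(row = c(1L, 1L), col = c(1L, 2L), burn_date = c(10L, 16L))
  )
  expect_identical(length(unique(split6$event_id)), 2L)
})

test_that("duplicate records are rejected by name", {
  rec <- data.frame(row = c(1L, 1L), col = c(2L, 2L),
                    burn_date = c(7L, 7L))
  expect_error(cluster_burned_pixels(rec), "1, 2, 7")
})

test_that("flood fill equals the all-pairs union oracle on random grids", {
  set.seed(42)
  for (k in 1:25) {
    rec <- random_records(60, 12L, 12L, date_range = c(0L, 30L))
    for (conn in c(4L, 8L)) {
      got <- cluster_burned_pixels(rec, max_gap_days = 5L,
                                   connectivity = conn)$event_id
      want <- oracle_cluster(rec, max_gap_days = 5L, connectivity = conn)
      expect_true(same_partition(got, want))
    }
  }
})

test_that("every record lands in exactly one event and sizes conserve", {
  cfg <- tiny_cfg(25L, 25L, seed = 13L, years = 2001:2004)
  b <- generate_burn_history(cfg, 6L, 6L)
  cl <- cluster_burned_pixels(b$records)
  expect_false(any(is.na(cl$event_id)))
  ev <- compute_characteristics(cl, cfg)
  expect_identical(sum(ev$size_pixels), nrow(b$records))
  for (y in unique(ev$calendar_year)) {
    n_rec <- sum(calendar_year_of(cl$burn_date) == y)
    expect_identical(sum(ev$size_pixels[ev$calendar_year == y]), n_rec)
  }
})

test_that("event count never increases with a larger gap tolerance", {
  set.seed(7)
  rec <- random_records(120, 15L, 15L, date_range = c(0L, 25L))
  counts <- vapply(c(0L, 1L, 3L, 5L, 8L, 12L, 30L), function(g)
    length(unique(cluster_burned_pixels(rec, max_gap_days = g)$event_id)), 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("clustering recovers synthetic ground truth exactly", {
  cfg <- landscape_config(grid_nrows = 50L, grid_ncols = 50L, seed = 7L)
  b <- generate_burn_history(cfg, 20L, 10L)
  cl <- cluster_burned_pixels(b$records)
  expect_true(same_partition(cl$event_id, b$records$true_event))
})

test_that("a 9,263-pixel fire at 500 m covers 2,316 km2", {
  cfg <- landscape_config(grid_nrows = 100L, grid_ncols = 100L)
  idx <- arrayInd(seq_len(9263L), c(100L, 100L))
  rec <- data.frame(row = idx[, 1], col = idx[, 2], burn_date = 200L)
  ev <- compute_characteristics(cluster_burned_pixels(rec), cfg)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$size_pixels, 9263L)
  expect_equal(round(ev$size_km2), 2316)
})

test_that("time since last fire averages over previously burned pixels only", {
  cfg <- tiny_cfg(5L, 5L)
  ign <- day_from_date("2006-07-01")
  rec <- data.frame(row = c(1L, 1L, 1L), col = 1:3, burn_date = ign)
  history <- rbind(
    rec,
    data.frame(row = 1L, col = 1L, burn_date = ign - round(1.0 * 365.25)),
    data.frame(row = 1L, col = 2L, burn_date = ign - round(2.0 * 365.25))
    # pixel (1,3) never burned before
  )
  ev <- compute_characteristics(cluster_burned_pixels(rec), cfg,
                                history = history)
  expect_equal(ev$tslf_years, 1.5, tolerance = 0.01)
  # no prior burns anywhere -> missing
  ev0 <- compute_characteristics(cluster_burned_pixels(rec), cfg)
  expect_true(is.na(ev0$tslf_years))
})

test_that("most recent prior burn is the one used", {
  cfg <- tiny_cfg(5L, 5L)
  ign <- day_from_date("2010-07-01")
  rec <- data.frame(row = 1L, col = 1L, burn_date = ign)
  history <- rbind(rec,
                   data.frame(row = 1L, col = 1L,
                              burn_date = ign - c(3000L, 500L)))
  ev <- compute_characteristics(cluster_burned_pixels(rec), cfg, history)
  expect_equal(ev$tslf_years, 500 / 365.25)
})

test_that("maximum radiative power is attached within footprint and dates", {
  cfg <- tiny_cfg(5L, 5L)
  rec <- data.frame(row = c(2L, 2L), col = c(2L, 3L), burn_date = c(50L, 51L))
  cl <- cluster_burned_pixels(rec)
  ev <- compute_characteristics(cl, cfg)
  ctr <- fr_cell_center(fireregime:::cfg_raster(cfg), 2L, 2L)
  det <- data.frame(x = ctr$x, y = ctr$y, date = c(50L, 51L, 52L),
                    frp = c(3, 9, 5))
  got <- attach_frp(ev, cl, det, cfg)
  expect_equal(got$frp_max, 9)
  # outside the date window (tolerance 1): no match
  far <- data.frame(x = ctr$x, y = ctr$y, date = 60L, frp = 99)
  expect_true(is.na(attach_frp(ev, cl, far, cfg)$frp_max))
  # no detections at all: missing stays missing
  none <- data.frame(x = numeric(), y = numeric(), date = integer(),
                     frp = numeric())
  expect_true(is.na(attach_frp(ev, cl, none, cfg)$frp_max))
})

test_that("empty event sets are rejected", {
  cfg <- tiny_cfg(5L, 5L)
  empty <- data.frame(row = integer(), col = integer(),
                      burn_date = integer(), event_id = integer())
  expect_error(compute_characteristics(empty, cfg), "empty")
})
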
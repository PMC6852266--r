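test_that("annual series totals and medians are plain arithmetic", {
  cfg <- tiny_cfg(10L, 10L)
  # three 4-pixel fires in 2003, nothing in 2004
  rec <- rbind(
    data.frame(row = 1L, col = 1:4, burn_date = day_from_date("2003-06-01")),
    data.frame(row = 5L, col = 1:4, burn_date = day_from_date("2003-07-01")),
    data.frame(row = 9L, col = 1:4, burn_date = day_from_date("2003-08-01"))
  )
  ev <- compute_characteristics(cluster_burned_pixels(rec), cfg)
  ann <- annual_series(ev, years = 2003:2004)
  expect_identical(ann$n_fires, c(3L, 0L))
  expect_equal(ann$area_burnt_km2, c(3, 0))
  expect_equal(ann$median_size_km2, c(1, NA))
  expect_true(is.na(ann$median_tslf_years[1]))
})

test_that("top-decile share matches the definition and a sort-sum oracle", {
  mk <- function(sizes) data.frame(event_id = seq_along(sizes),
                                   size_km2 = sizes)
  expect_equal(top_decile_share(mk(rep(2, 10))), 0.1)
  expect_equal(top_decile_share(mk(c(9, rep(1, 9)))), 0.5)
  set.seed(12)
  sizes <- rlnorm(500, 0, 1.5)
  want <- sum(sort(sizes, decreasing = TRUE)[1:50]) / sum(sizes)
  expect_equal(top_decile_share(mk(sizes)), want)
  expect_error(top_decile_share(mk(numeric(0))), "at least one")
})

test_that("unit summaries agree with a point-in-polygon oracle", {
  cfg <- tiny_cfg(24L, 24L, seed = 17L, years = 2001:2005)
  b <- generate_burn_history(cfg, 5L, 5L)
  fl <- delineate_fires(b$records, cfg)
  us <- unit_summary(fl$events, fl$records, cfg)
  expect_true(all(us$proportion_burnt >= 0 & us$proportion_burnt <= 1,
                  na.rm = TRUE))
  # per-unit fire counts vs direct polygon assignment of centroids
  for (u in cfg$units) {
    if (u$is_buffer) next
    want <- sum(point_in_polygon(fl$events$centroid_x,
                                 fl$events$centroid_y, u$ring))
    expect_identical(us$n_fires[us$unit == u$name], want)
  }
  expect_identical(sum(us$n_fires), nrow(fl$events))
  # unit areas tile the study region
  expect_equal(sum(us$area_km2),
               cfg$grid_nrows * cfg$grid_ncols * (cfg$pixel_size_m / 1000)^2)
})

test_that("overlapping management units are rejected", {
  cfg <- tiny_cfg(10L, 10L)
  cfg$units[["PA_2"]]$ring <- cfg$units[["PA_1"]]$ring
  rec <- data.frame(row = 1L, col = 1L, burn_date = 100L)
  ev <- compute_characteristics(cluster_burned_pixels(rec), cfg)
  expect_error(unit_summary(ev, cluster_burned_pixels(rec), cfg), "overlap")
})

test_that("coarse rasterization conserves burnt area and fire counts", {
  cfg <- tiny_cfg(24L, 24L, seed = 19L, years = 2001:2003)
  b <- generate_burn_history(cfg, 6L, 8L)
  fl <- delineate_fires(b$records, cfg)
  ras <- rasterize_characteristic(fl$events, fl$records, cfg, cell_km = 6)
  ann <- annual_series(fl$events)
  for (y in names(ras$area_burnt)) {
    expect_equal(sum(ras$area_burnt[[y]]$values),
                 ann$area_burnt_km2[ann$year == as.integer(y)])
    expect_equal(sum(ras$n_fires[[y]]$values),
                 ann$n_fires[ann$year == as.integer(y)])
  }
})

test_that("rasterized medians match a brute-force binning oracle", {
  cfg <- tiny_cfg(24L, 24L, seed = 23L, years = 2001:2002)
  b <- generate_burn_history(cfg, 8L, 4L)
  fl <- delineate_fires(b$records, cfg)
  ras <- rasterize_characteristic(fl$events, fl$records, cfg, cell_km = 6)
  grid <- ras$median_size[[1]]
  ev <- fl$events[fl$events$calendar_year == 2001, ]
  cells <- fr_cell_at(grid, ev$centroid_x, ev$centroid_y)
  for (r in unique(cells$row)) {
    for (cc in unique(cells$col[cells$row == r])) {
      inside <- cells$row == r & cells$col == cc
      if (!any(inside)) next
      expect_equal(grid$values[r, cc], median(ev$size_km2[inside]))
    }
  }
})

test_that("a fire straddling coarse cells splits its area by pixel", {
  cfg <- tiny_cfg(24L, 24L)
  # 4 pixels spanning the 6 km cell boundary at column 12|13
  rec <- data.frame(row = 2L, col = 11:14,
                    burn_date = day_from_date("2003-06-01"))
  fl <- delineate_fires(rec, cfg)
  ras <- rasterize_characteristic(fl$events, fl$records, cfg, cell_km = 6)
  a <- ras$area_burnt[["2003"]]$values
  expect_equal(sum(a), 1)          # 4 pixels x 0.25 km2
  expect_equal(sort(a[a > 0]), c(0.5, 0.5))
})

test_that("unburnt extent is the complement of the burned union", {
  cfg <- tiny_cfg(10L, 10L, years = 2001:2002)
  none <- data.frame(row = integer(), col = integer(), burn_date = integer())
  expect_equal(unburnt_extent(none, cfg)$fraction, 1)
  all_px <- expand.grid(row = 1:10, col = 1:10)
  all_rec <- data.frame(all_px, burn_date = 100L)
  expect_equal(unburnt_extent(all_rec, cfg)$km2, 0)
  set.seed(3)
  some <- unique(data.frame(row = sample(1:10, 60, TRUE),
                            col = sample(1:10, 60, TRUE)))
  rec <- rbind(data.frame(some, burn_date = 100L),
               data.frame(some[1:5, ], burn_date = 600L))  # reburns
  got <- unburnt_extent(rec, cfg)
  expect_equal(got$fraction, (100 - nrow(some)) / 100)
})
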
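test_that("burn history produces the requested patches with consistent truth", {
  cfg <- tiny_cfg(10L, 10L, seed = 3L, years = 2001:2003)
  b <- generate_burn_history(cfg, n_fires_per_year = 1L, mean_fire_pixels = 4L,
                             size_sdlog = 1e-6)
  expect_equal(nrow(b$records), 3L * 4L)
  expect_equal(as.integer(table(b$records$year)), rep(4L, 3))
  # truth labels and rasters mutually consistent
  for (y in names(b$stack)) {
    sub <- b$records[b$records$year == as.integer(y), ]
    vals <- b$stack[[y]]$values[cbind(sub$row, sub$col)]
    expect_identical(vals, as.numeric(sub$burn_date))
    expect_equal(sum(!is.na(b$stack[[y]]$values)), nrow(sub))
  }
  # intra-fire date span is capped at 5 days
  spans <- tapply(b$records$burn_date, b$records$true_event,
                  function(d) diff(range(d)))
  expect_true(all(spans <= 5))
})

test_that("zero fires gives empty rasters and empty truth", {
  cfg <- tiny_cfg(10L, 10L, years = 2001:2002)
  b <- generate_burn_history(cfg, 0L, 4L)
  expect_identical(nrow(b$records), 0L)
  expect_true(all(vapply(b$stack, function(r) all(is.na(r$values)), TRUE)))
})

test_that("impossible fire loads raise a capacity error", {
  cfg <- tiny_cfg(10L, 10L)
  expect_error(generate_burn_history(cfg, 50L, 10L), "capacity")
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- tiny_cfg(15L, 15L, seed = 11L, years = 2001:2002)
  a <- generate_burn_history(cfg, 3L, 5L)
  b <- generate_burn_history(cfg, 3L, 5L)
  expect_identical(a$records, b$records)
  expect_identical(generate_rainfall(cfg), generate_rainfall(cfg))
  expect_identical(generate_boma_observations(cfg, n_footprints = 20L),
                   generate_boma_observations(cfg, n_footprints = 20L))
  expect_identical(generate_trajectories(cfg, 1L),
                   generate_trajectories(cfg, 1L))
})

test_that("active-fire detections respect probability and footprints", {
  cfg <- tiny_cfg(30L, 30L, seed = 5L, years = 2001:2003)
  b <- generate_burn_history(cfg, 6L, 5L)
  expect_identical(nrow(generate_active_fires(b, cfg, 0)), 0L)
  det <- generate_active_fires(b, cfg, 1)
  expect_gt(nrow(det), 0L)
  # every detection lies on a pixel of some true fire, within its date span
  tmpl <- fireregime:::cfg_raster(cfg)
  cells <- fr_cell_at(tmpl, det$x, det$y)
  key <- paste(cells$row, cells$col, det$date)
  truth_key <- paste(b$records$row, b$records$col, b$records$burn_date)
  expect_true(all(key %in% truth_key))
  expect_true(all(det$frp > 0))
})

test_that("rainfall has the stated gradient, bimodality and uniform limit", {
  cfg <- tiny_cfg(20L, 20L, seed = 2L, years = 2001:2003)
  flat <- generate_rainfall(cfg, west_east_gradient = 0, trend = 0,
                            noise_sdlog = 0)
  ann <- annual_rainfall(flat)
  expect_true(all(abs(ann[[1]]$values - ann[[1]]$values[1, 1]) < 1e-9))
  grad <- generate_rainfall(cfg, west_east_gradient = -8, noise_sdlog = 0)
  anng <- annual_rainfall(grad)[[1]]$values
  expect_true(all(diff(t(anng)[, 1]) < 0))  # declining west -> east
  # monthly climatology has exactly two (circular) local maxima
  clim <- vapply(1:12, function(m) {
    mean(grad$arr[, , grad$time$month == m])
  }, 0)
  up <- clim > clim[c(12, 1:11)] & clim > clim[c(2:12, 1)]
  expect_identical(sum(up), 2L)
  expect_true(all(which(up) %in% c(3:5, 10:12)))
})

test_that("boma observations follow the planted density model", {
  cfg <- tiny_cfg(40L, 40L, seed = 7L)
  obs <- generate_boma_observations(cfg, slope = 0, n_footprints = 40L)
  expect_true(all(obs$count >= 0))
  expect_true(all(obs$area_km2 > 0))
  tr <- attr(obs, "truth")
  expect_identical(nrow(tr), 40L)
  expect_true(all(tr$slope == 0))
  # some footprints observed in >= 2 years, a few single-year
  per_fp <- tapply(obs$year, obs$footprint_id, function(y) length(unique(y)))
  expect_true(any(per_fp >= 2))
  expect_true(any(per_fp == 1))
})

test_that("trajectories carry their truth and honour unbalanced sampling", {
  cfg <- tiny_cfg(60L, 60L, seed = 9L)
  months <- data.frame(year = 2001L, month = 1:2)
  traj <- generate_trajectories(cfg, 1L, months = months,
                                fixes_per_month = c(100L, 10L))
  expect_identical(attr(traj, "sigma2_m"), 50)
  counts <- table(traj$month)
  expect_identical(as.integer(counts), c(100L, 10L))
  expect_true(all(diff(traj$t[traj$month == 1]) > 0))
})
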
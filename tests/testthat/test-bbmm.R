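sim_bm <- function(n_fix, sigma2, dt = 3600, loc_sd = 0, seed = 1) {
  set.seed(seed)
  sd_step <- sqrt(sigma2 * dt)
  data.frame(
    t = (seq_len(n_fix) - 1) * dt,
    x = cumsum(c(0, rnorm(n_fix - 1, 0, sd_step))) + rnorm(n_fix, 0, loc_sd),
    y = cumsum(c(0, rnorm(n_fix - 1, 0, sd_step))) + rnorm(n_fix, 0, loc_sd)
  )
}

test_that("motion variance is recovered within 20% from 500 fixes", {
  traj <- sim_bm(500, sigma2 = 50, loc_sd = 20, seed = 101)
  est <- estimate_motion_variance(traj, loc_error_sd = 20)
  expect_lt(abs(est - 50) / 50, 0.2)
})

test_that("a stationary animal pins the variance at the lower bound", {
  set.seed(102)
  traj <- data.frame(t = (0:99) * 3600, x = rnorm(100, 0, 5),
                     y = rnorm(100, 0, 5))
  expect_warning(est <- estimate_motion_variance(traj, loc_error_sd = 20),
                 "degenerate")
  expect_equal(est, 1e-6)
})

test_that("doubling displacements quadruples the estimated variance", {
  traj <- sim_bm(300, sigma2 = 20, loc_sd = 0, seed = 103)
  est1 <- estimate_motion_variance(traj, loc_error_sd = 0)
  traj2 <- traj
  traj2$x <- traj$x * 2; traj2$y <- traj$y * 2
  est2 <- estimate_motion_variance(traj2, loc_error_sd = 0)
  expect_equal(est2 / est1, 4, tolerance = 1e-3)
})

test_that("bridge UDs are normalized, concentrated and symmetric", {
  grid <- fr_raster(matrix(0, 21, 21), -5250, -5250, 500)
  # two coincident fixes: all mass in the containing cell
  still <- data.frame(t = c(0, 3600), x = c(0, 0), y = c(0, 0))
  ud0 <- bbmm_ud(still, sigma2 = 1e-6, grid, loc_error_sd = 5)
  expect_equal(sum(ud0$values), 1, tolerance = 1e-9)
  expect_gt(ud0$values[11, 11], 0.99)
  # symmetric two-fix bridge: mirror-image equality about the midpoint
  sym <- data.frame(t = c(0, 7200), x = c(-1000, 1000), y = c(0, 0))
  ud <- bbmm_ud(sym, sigma2 = 30, grid, loc_error_sd = 10)
  expect_equal(sum(ud$values), 1, tolerance = 1e-9)
  expect_equal(ud$values, ud$values[, 21:1], tolerance = 1e-6)
  expect_error(bbmm_ud(data.frame(t = c(0, 3600), x = c(0, 9e5),
                                  y = c(0, 0)),
                       30, grid), "outside")
})

test_that("corridor width grows with motion variance", {
  grid <- fr_raster(matrix(0, 41, 41), -10250, -10250, 500)
  bridge <- data.frame(t = c(0, 7200), x = c(-2000, 2000), y = c(0, 0))
  spread <- vapply(c(5, 50, 500), function(s2) {
    ud <- bbmm_ud(bridge, s2, grid, loc_error_sd = 0)
    df <- fr_as_df(ud, drop_na = FALSE)
    sqrt(sum(df$value * df$y^2))    # SD across the corridor
  }, 0)
  expect_true(all(diff(spread) > 0))
})

test_that("UD agrees with a dense Monte-Carlo bridge oracle", {
  grid <- fr_raster(matrix(0, 40, 40), -9000, -10000, 500)
  tb <- data.frame(t = c(0, 10800), x = c(0, 2000), y = c(0, 0))
  ud <- bbmm_ud(tb, sigma2 = 50, grid, loc_error_sd = 20, n_quad = 50)
  set.seed(104)
  N <- 3e5
  a <- runif(N)
  s2 <- 10800 * a * (1 - a) * 50 + ((1 - a)^2 + a^2) * 400
  xs <- a * 2000 + rnorm(N, 0, sqrt(s2))
  ys <- rnorm(N, 0, sqrt(s2))
  ok <- xs > -9000 & xs < 11000 & ys > -10000 & ys < 10000
  h <- table(factor(floor((ys[ok] + 10000) / 500) + 1, levels = 1:40),
             factor(floor((xs[ok] + 9000) / 500) + 1, levels = 1:40))
  mc <- h / sum(h)
  expect_lt(0.5 * sum(abs(mc - ud$values)), 0.02)
})

test_that("monthly weights invert pooled fix counts", {
  traj <- data.frame(
    id = 1L, year = 2001L,
    month = rep(c(1L, 2L), c(100L, 10L)),
    t = 1:110, x = 0, y = 0
  )
  w <- voronoi_fracture_weights(traj)
  expect_equal(unname(w[c("2001-01", "2001-02")]), c(0.1, 1))
  even <- traj
  even$month <- rep(c(1L, 2L), each = 55L)
  expect_true(all(voronoi_fracture_weights(even) == 1))
})

test_that("Voronoi fractures tile the UD exactly", {
  grid <- fr_raster(matrix(0, 21, 21), -5250, -5250, 500)
  traj <- data.frame(t = c(0, 3600, 7200, 10800),
                     x = c(-2000, 0, 1500, 2500),
                     y = c(0, 500, -500, 0))
  ud <- bbmm_ud(traj, 40, grid, loc_error_sd = 10)
  fr <- voronoi_fractures(grid, traj)
  masses <- fracture_masses(ud, fr)
  expect_equal(sum(masses), 1, tolerance = 1e-12)
  expect_identical(length(masses), 4L)
  # weighted sum over fractures equals whole-UD reweighting (single month)
  w <- 0.37
  expect_equal(sum(masses * w), w * sum(ud$values), tolerance = 1e-12)
})

test_that("population UDs sum, exclude the low tail and renormalize", {
  grid <- fr_raster(matrix(0, 21, 21), -5250, -5250, 500)
  traj <- data.frame(t = c(0, 7200), x = c(-1500, 1500), y = c(0, 0))
  ud <- bbmm_ud(traj, 40, grid, loc_error_sd = 10)
  pop <- population_ud(list(ud), exclude_frac = 0.05)
  expect_equal(attr(pop, "retained_mass"), 0.95, tolerance = 0.01)
  expect_equal(sum(pop$values), 1, tolerance = 1e-9)
  # two identical individuals: same UD as one after rescaling
  pop2 <- population_ud(list(ud, ud), exclude_frac = 0.05)
  expect_equal(pop2$values, pop$values, tolerance = 1e-12)
  # value-quantile convention is available and differs in general
  popq <- population_ud(list(ud), exclusion = "value_quantile")
  expect_equal(sum(popq$values), 1, tolerance = 1e-9)
  expect_error(population_ud(list()), "no individual UDs")
})

test_that("three-month utilization is a three-cell lookup", {
  grid <- fr_raster(matrix(1 / 441, 21, 21), 0, 0, 500)
  uds <- list("2005-05" = grid, "2005-06" = grid, "2005-07" = grid)
  fire <- data.frame(centroid_x = 5250, centroid_y = 5250,
                     ignition_date = day_from_date("2005-07-15"))
  expect_equal(utilization_3mo(fire, uds), 3 / 441)
  # outside every UD: zero
  far <- data.frame(centroid_x = 9e5, centroid_y = 9e5,
                    ignition_date = day_from_date("2005-07-15"))
  expect_equal(utilization_3mo(far, uds), 0)
  # missing month: flagged missing
  fire_apr <- data.frame(centroid_x = 5250, centroid_y = 5250,
                         ignition_date = day_from_date("2005-06-15"))
  expect_warning(v <- utilization_3mo(fire_apr, uds), "missing")
  expect_true(is.na(v))
})
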
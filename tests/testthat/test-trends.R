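test_that("annual correlations use the n-2 df convention", {
  ann <- data.frame(
    year = 2001:2014, n_fires = 2 * (2001:2014) - 3000,
    area_burnt_km2 = 14:1, median_size_top_decile = rnorm(14),
    median_ignition_day = 100, median_tslf_years = rnorm(14),
    median_frp = rnorm(14)
  )
  ct <- annual_correlations(ann)
  lin <- ct[ct$pair == "n_fires vs year", ]
  expect_equal(lin$r, 1)
  expect_equal(lin$r2, 1)
  expect_identical(lin$df, 12L)
  const <- ct[ct$pair == "median_ignition_day vs year", ]
  expect_identical(const$flag, "undefined")
  expect_true(is.na(const$r))
})

test_that("per-pixel Gaussian slopes equal closed-form least squares", {
  set.seed(61)
  years <- 2001:2010
  stack <- lapply(years, function(y)
    fr_raster(matrix(rnorm(36, mean = 0.2 * (y - 2001)), 6, 6),
              pixel_size = 6000))
  names(stack) <- years
  tr <- per_pixel_trend(stack)
  t <- years - 2001
  for (cell in list(c(1L, 1L), c(4L, 2L), c(6L, 6L))) {
    y <- vapply(stack, function(r) r$values[cell[1], cell[2]], 0)
    b_want <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
    expect_equal(tr$slope$values[cell[1], cell[2]], b_want,
                 tolerance = 1e-12)
    expect_equal(tr$baseline$values[cell[1], cell[2]],
                 mean(y) - b_want * mean(t), tolerance = 1e-12)
  }
  # constant cells have exactly zero slope
  const <- lapply(years, function(y) fr_raster(matrix(3, 2, 2),
                                               pixel_size = 6000))
  names(const) <- years
  expect_true(all(per_pixel_trend(const)$slope$values == 0))
})

test_that("Poisson per-pixel trends recover a planted log-linear rate", {
  set.seed(62)
  years <- 2001:2014
  lam <- function(t) exp(2 + 0.05 * t)
  reps <- vapply(1:40, function(r) {
    stack <- lapply(years, function(y)
      fr_raster(matrix(rpois(1, lam(y - 2001)), 1, 1), pixel_size = 6000))
    names(stack) <- years
    per_pixel_trend(stack, family = "poisson")$slope$values[1, 1]
  }, 0)
  expect_lt(abs(mean(reps) - 0.05), 2 * sd(reps) / sqrt(40))
})

test_that("missing-heavy cells are flagged missing", {
  years <- 2001:2006
  stack <- lapply(years, function(y) fr_raster(matrix(NA_real_, 2, 2),
                                               pixel_size = 6000))
  names(stack) <- years
  stack[["2001"]]$values[1, 1] <- 1
  stack[["2002"]]$values[1, 1] <- 2
  tr <- per_pixel_trend(stack)
  expect_true(all(is.na(tr$slope$values)))
})

test_that("LRT reduction respects nesting and records its path", {
  set.seed(63)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 1.5 * d$x1 + rnorm(n)
  fit <- glm(y ~ x1 + x2 + x1:x2, data = d, family = gaussian())
  out <- reduce_by_lrt(fit)
  expect_true("x1" %in% attr(terms(out$reduced), "term.labels"))
  expect_gte(deviance(out$reduced), deviance(out$full) - 1e-9)
  if (any(out$path$dropped)) expect_lte(AIC(out$reduced), AIC(out$full))
  # the planted term survives; interaction of noise does not
  expect_false("x1:x2" %in% attr(terms(out$reduced), "term.labels"))
})

test_that("area-change model keeps a strong planted driver with its sign", {
  set.seed(64)
  n <- 150
  cells <- data.frame(
    boma_rate = rnorm(n), unit = sample(c("A", "B", "C"), n, TRUE),
    rain_mean = rnorm(n), rain_trend = rnorm(n), baseline = rnorm(n)
  )
  cells$area_change <- -2 * cells$boma_rate + 0.5 * cells$rain_mean + rnorm(n)
  cells$area_change[3] <- NA
  acm <- area_change_model(cells)
  expect_identical(acm$n_dropped, 1L)
  expect_true("boma_rate" %in% attr(terms(acm$reduced), "term.labels"))
  expect_lt(coef(acm$reduced)[["boma_rate"]], 0)
})

test_that("Tukey contrasts are familywise-conservative", {
  set.seed(65)
  d <- data.frame(unit = rep(c("A", "B", "C"), each = 30))
  d$y <- rnorm(90) + ifelse(d$unit == "C", 5, 0)
  fit <- glm(y ~ unit, data = d, family = gaussian())
  tk <- tukey_hsd(fit, "unit")
  sigs <- tk$p.value < 0.05
  expect_identical(sum(sigs), 2L)
  expect_true(all(grepl("C", tk$contrast[sigs])))
  # adjusted p >= unadjusted p for every contrast
  un <- as.data.frame(emmeans::contrast(emmeans::emmeans(fit, "unit"),
                                        method = "pairwise", adjust = "none"))
  expect_true(all(tk$p.value >= un$p.value - 1e-12))
  # two samples from one population: adjusted p far from significance
  d0 <- data.frame(unit = rep(c("A", "B"), each = 40), y = rnorm(80))
  f0 <- glm(y ~ unit, data = d0, family = gaussian())
  expect_gt(tukey_hsd(f0, "unit")$p.value, 0.05)
  # factor absent from the model is an informative error
  f1 <- glm(y ~ 1, data = d0, family = gaussian())
  expect_error(tukey_hsd(f1, "unit"), "not in the model")
})

test_that("the overdispersion check separates Poisson from overdispersed", {
  set.seed(66)
  n <- 300
  x <- rnorm(n)
  mu <- exp(1 + 0.3 * x)
  pois <- glm(rpois(n, mu) ~ x, family = poisson())
  chk <- overdispersion_check(pois)
  expect_lt(abs(chk$dispersion - 1), 0.25)
  expect_false(chk$overdispersed)
  nb <- glm(MASS::rnegbin(n, mu, theta = 1) ~ x, family = poisson())
  chk_nb <- overdispersion_check(nb)
  expect_gt(chk_nb$dispersion, 2)
  expect_true(chk_nb$overdispersed)
  zero <- glm(rep(2L, n) ~ 1, family = poisson())
  expect_lt(overdispersion_check(zero)$dispersion, 1)
  expect_error(overdispersion_check(glm(rnorm(20) ~ 1)), "Poisson")
})

test_that("change decomposition recovers planted couplings", {
  set.seed(67)
  mk <- function(v) fr_raster(matrix(v, 10, 10), pixel_size = 6000)
  a <- rnorm(100)
  out <- change_decomposition(mk(a), mk(a), mk(rnorm(100)))
  expect_equal(out$r[1], 1)
  expect_lt(abs(out$r[2]), 0.35)
  expect_identical(out$df[1], 98L)
  coupled <- change_decomposition(mk(a), mk(a + rnorm(100, 0, 0.3)),
                                  mk(-a + rnorm(100, 0, 0.3)))
  expect_gt(coupled$r[1], 0.8)
  expect_lt(coupled$r[2], -0.8)
})
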
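#' Per-footprint trends in boma density
#'
#' Fits one Poisson GLM (log link, log-area offset) of count against year to
#' each image-overlap footprint with counts in at least two distinct years.
#' The rate of change is reported on the density scale (bomas km^-2 yr^-1)
#' by the delta method at the footprint's mean observation year, with a
#' predicted 2001 baseline density. Footprints observed in a single year
#' contribute a baseline only (`rate = NA`, flagged); footprints whose
#' counts are all zero get a zero rate with a degeneracy flag.
#'
#' @param obs observation table from [generate_boma_observations()] (or any
#'   data.frame with `footprint_id`, `year`, `count`, `area_km2`, `cx`,
#'   `cy`, `unit`).
#' @param base_year year at which the baseline density is predicted.
#' @return data.frame with one row per footprint: `footprint_id`, `x`, `y`,
#'   `unit`, `rate`, `rate_se`, `baseline`, `flag` (`"ok"`,
#'   `"baseline_only"` or `"degenerate"`).
#' @export
fit_local_trends <- function(obs, base_year = 2001L) {
  out <- lapply(split(obs, obs$footprint_id), function(fp) {
    res <- data.frame(
      footprint_id = fp$footprint_id[1], x = fp$cx[1], y = fp$cy[1],
      unit = fp$unit[1], rate = NA_real_, rate_se = NA_real_,
      baseline = NA_real_, flag = "ok"
    )
    yrs <- unique(fp$year)
    if (length(yrs) < 2L) {
      res$baseline <- sum(fp$count) / (fp$area_km2[1] * nrow(fp))
      res$flag <- "baseline_only"
      return(res)
    }
    if (all(fp$count == 0L)) {
      res$rate <- 0; res$baseline <- 0; res$flag <- "degenerate"
      return(res)
    }
    yc <- fp$year - base_year
    X <- cbind(1, yc)
    fit <- suppressWarnings(stats::glm.fit(
      X, fp$count, family = stats::poisson(),
      offset = log(fp$area_km2)
    ))
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    ybar <- mean(yc)
    # density(y) = exp(a + b y); rate = d density / dy at the mean year
    dens_bar <- exp(a + b * ybar)
    res$rate <- b * dens_bar
    res$baseline <- exp(a)
    # delta method: grad of b * exp(a + b ybar) wrt (a, b)
    XtWX <- crossprod(X * fit$weights, X)
    V <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, 2, 2))
    g <- c(res$rate, dens_bar * (1 + b * ybar))
    res$rate_se <- sqrt(drop(t(g) %*% V %*% g))
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Interpolated surfaces of boma-density rate and baseline
#'
#' Kriges the per-footprint rates and baselines over a coarse grid with the
#' stratified scheme of [krige_surface()] (regression kriging on management
#' unit inside protected areas, universal kriging in the buffer).
#'
#' @param trends footprint table from [fit_local_trends()].
#' @param cfg the [landscape_config()].
#' @param cell_km grid cell edge, km (default 6).
#' @return list with `rate` and `baseline` [fr_raster()]s, the kriging
#'   diagnostics for each, and the grid.
#' @export
boma_surfaces <- function(trends, cfg, cell_km = 6) {
  grid <- coarse_grid(cfg, cell_km)
  ok <- trends[trends$flag %in% c("ok", "degenerate") & !is.na(trends$rate), ]
  kr <- krige_surface(
    data.frame(x = ok$x, y = ok$y, value = ok$rate, unit = ok$unit),
    cfg, grid
  )
  base_pts <- trends[!is.na(trends$baseline), ]
  kb <- krige_surface(
    data.frame(x = base_pts$x, y = base_pts$y, value = base_pts$baseline,
               unit = base_pts$unit),
    cfg, grid
  )
  list(rate = kr$surface, baseline = kb$surface,
       rate_diag = kr, baseline_diag = kb, grid = grid)
}

#' Predicted boma-density surface for a year
#'
#' `density(year) = max(0, baseline + rate * (year - base_year))`; negative
#' extrapolations are clamped to zero.
#'
#' @param surfaces output of [boma_surfaces()] (or any list with `rate` and
#'   `baseline` rasters on a common grid).
#' @param year prediction year.
#' @param base_year year the baseline refers to.
#' @return an [fr_raster()] of bomas/km^2.
#' @export
predict_density <- function(surfaces, year, base_year = 2001L) {
  out <- surfaces$baseline
  out$values <- pmax(surfaces$baseline$values +
                       surfaces$rate$values * (year - base_year), 0)
  out
}

#' Hold-out verification of predicted boma density
#'
#' Pearson correlation between predicted and independently counted density
#' on hold-out cells, plus the ratio of predicted to actual means. Cells
#' that straddle the protected/buffer boundary can be excluded (the two
#' strata are interpolated from different models, so a straddling cell has
#' no single valid prediction); exclusions are reported, not silent.
#'
#' @param predicted,actual density vectors over hold-out cells.
#' @param straddles optional logical vector flagging cells split across
#'   strata; flagged cells are excluded.
#' @return list with `r`, `p_value`, `df`, `ratio`
#'   (mean predicted / mean actual) and `n_excluded`.
#' @export
verify_holdout <- function(predicted, actual, straddles = NULL) {
  if (is.null(straddles)) straddles <- rep(FALSE, length(predicted))
  keep <- !straddles & !is.na(predicted) & !is.na(actual)
  predicted <- predicted[keep]; actual <- actual[keep]
  if (length(predicted) < 3L)
    stop("need at least 3 hold-out cells after exclusions")
  ct <- stats::cor.test(predicted, actual)
  list(
    r = unname(ct$estimate), p_value = ct$p.value,
    df = unname(ct$parameter),
    ratio = mean(predicted) / mean(actual),
    n_excluded = sum(straddles)
  )
}

#' Draw hold-out cells and verify the density model
#'
#' Selects a fraction of grid cells not intersecting any fitting footprint,
#' simulates (or accepts) single-image counts there and calls
#' [verify_holdout()].
#'
#' @param surfaces output of [boma_surfaces()].
#' @param obs the fitting observations (footprint bounds are used to find
#'   cells with no observations).
#' @param cfg the [landscape_config()].
#' @param actual_fun function(x, y, year) returning the true density at a
#'   cell centre (used to simulate the hold-out counts).
#' @param year verification year.
#' @param fraction fraction of no-observation cells held out (default 0.25).
#' @param seed RNG seed for the hold-out draw.
#' @return the [verify_holdout()] report, plus `n_holdout`.
#' @export
holdout_verification <- function(surfaces, obs, cfg, actual_fun,
                                 year = 2014L, fraction = 0.25, seed = 1L) {
  grid <- surfaces$grid
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ctr <- fr_cell_center(grid, idx$row, idx$col)
  half <- grid$pixel_size / 2
  fp <- unique(obs[, c("xmin", "xmax", "ymin", "ymax")])
  covered <- rep(FALSE, nrow(idx))
  for (i in seq_len(nrow(fp))) {
    covered <- covered |
      (ctr$x + half > fp$xmin[i] & ctr$x - half < fp$xmax[i] &
         ctr$y + half > fp$ymin[i] & ctr$y - half < fp$ymax[i])
  }
  free <- which(!covered)
  if (length(free) < 3L)
    stop("too few cells without observations to hold out; use a finer grid")
  set.seed(seed)
  hold <- sample(free, max(3L, round(length(free) * fraction)))
  pred_r <- predict_density(surfaces, year)
  predicted <- pred_r$values[cbind(idx$row[hold], idx$col[hold])]
  actual <- vapply(hold, function(i) actual_fun(ctr$x[i], ctr$y[i], year), 0)
  # straddle rule: cell corners on both sides of the protected/buffer split
  straddles <- vapply(hold, function(i) {
    xs <- ctr$x[i] + c(-half, half, half, -half) * 0.999
    ys <- ctr$y[i] + c(-half, -half, half, half) * 0.999
    u <- assign_unit(xs, ys, cfg$units)
    any(u == "buffer", na.rm = TRUE) && any(u != "buffer", na.rm = TRUE)
  }, TRUE)
  rep <- verify_holdout(predicted, actual, straddles)
  rep$n_holdout <- length(hold)
  rep
}
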
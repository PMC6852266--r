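# Geostatistical interpolation: empirical semivariogram, weighted
# least-squares exponential model fit, and kriging (ordinary, universal
# with linear drift, or with arbitrary external drift columns). Weights are
# returned so the unbiasedness constraint (weights summing to one) can be
# verified at every prediction point.

#' Empirical semivariogram
#'
#' Classical Matheron estimator binned into `n_bins` lag classes up to
#' `cutoff` (default: half the maximum pairwise distance).
#'
#' @param coords two-column matrix of point coordinates.
#' @param z values at the points.
#' @param n_bins number of lag bins (default 12).
#' @param cutoff maximum lag distance.
#' @return data.frame with `dist` (bin mean lag), `gamma` (semivariance)
#'   and `n` (pair count); empty bins are dropped.
#' @export
empirical_variogram <- function(coords, z, n_bins = 12L, cutoff = NULL) {
  d <- as.matrix(stats::dist(coords))
  dz2 <- outer(z, z, "-")^2
  iu <- upper.tri(d)
  h <- d[iu]; g <- dz2[iu] / 2
  if (is.null(cutoff)) cutoff <- max(h) / 2
  keep <- h <= cutoff & h > 0
  h <- h[keep]; g <- g[keep]
  bins <- cut(h, breaks = seq(0, cutoff, length.out = n_bins + 1L),
              include.lowest = TRUE)
  out <- data.frame(
    dist = tapply(h, bins, mean),
    gamma = tapply(g, bins, mean),
    n = as.integer(table(bins))
  )
  out[!is.na(out$dist) & out$n > 0, , drop = FALSE]
}

#' Fit an exponential variogram model by weighted least squares
#'
#' Model `gamma(h) = nugget + psill * (1 - exp(-h / range))`, fitted by
#' Cressie-weighted least squares (weights `n / gamma_model^2`). When the
#' optimisation fails or collapses, falls back to a pure-nugget model (which
#' makes kriging behave like a distance-agnostic mean) with a warning.
#'
#' @param emp empirical variogram from [empirical_variogram()].
#' @return list with `nugget`, `psill`, `range`, logical `degenerate`.
#' @export
fit_variogram <- function(emp) {
  sill0 <- max(emp$gamma)
  if (!is.finite(sill0) || sill0 <= 0) {
    warning("flat variogram; falling back to pure nugget")
    return(list(nugget = max(sill0, 1e-12), psill = 0,
                range = max(emp$dist), degenerate = TRUE))
  }
  obj <- function(p) {
    nug <- exp(p[1]); ps <- exp(p[2]); rg <- exp(p[3])
    gm <- nug + ps * (1 - exp(-emp$dist / rg))
    sum(emp$n * (emp$gamma - gm)^2 / pmax(gm, 1e-12)^2)
  }
  init <- log(c(max(sill0 * 0.1, 1e-8), sill0, max(emp$dist) / 3))
  fit <- try(stats::optim(init, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000)), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) {
    warning("variogram fit failed; falling back to pure nugget")
    return(list(nugget = sill0, psill = 0, range = max(emp$dist),
                degenerate = TRUE))
  }
  p <- exp(fit$par)
  list(nugget = p[1], psill = p[2], range = p[3], degenerate = FALSE)
}

# covariance function implied by an exponential variogram
vg_cov <- function(h, vg) {
  ifelse(h == 0, vg$nugget + vg$psill, vg$psill * exp(-h / vg$range))
}

#' Kriging prediction with explicit weights
#'
#' Solves the kriging system for each prediction point. `drift = "constant"`
#' is ordinary kriging; `drift = "linear"` is universal kriging with a
#' first-order polynomial spatial drift. Additional external-drift columns
#' (e.g. management-unit dummies) can be supplied via `F_obs` / `F_pred`.
#' The constant drift function is always included, so the kriging weights
#' sum to one at every prediction point.
#'
#' @param coords,z observation coordinates (two-column matrix) and values.
#' @param pred_coords prediction coordinates (two-column matrix).
#' @param vg variogram model from [fit_variogram()].
#' @param drift `"constant"` or `"linear"`.
#' @param F_obs,F_pred optional extra drift design columns at observations
#'   and prediction points.
#' @return list with `pred` (predictions), `weights` (n_pred x n_obs
#'   matrix) and `var` (kriging variance).
#' @export
krige <- function(coords, z, pred_coords, vg, drift = c("constant", "linear"),
                  F_obs = NULL, F_pred = NULL) {
  drift <- match.arg(drift)
  n <- nrow(coords)
  C <- vg_cov(as.matrix(stats::dist(coords)), vg)
  Fo <- matrix(1, n, 1)
  Fp <- matrix(1, nrow(pred_coords), 1)
  if (drift == "linear") {
    sc <- max(apply(coords, 2, function(v) diff(range(v))), 1)
    Fo <- cbind(Fo, coords / sc)
    Fp <- cbind(Fp, pred_coords / sc)
  }
  if (!is.null(F_obs)) {
    Fo <- cbind(Fo, F_obs)
    Fp <- cbind(Fp, F_pred)
  }
  p <- ncol(Fo)
  A <- rbind(cbind(C, Fo), cbind(t(Fo), matrix(0, p, p)))
  Ai <- tryCatch(solve(A), error = function(e) MASS_ginv(A))
  dx <- outer(pred_coords[, 1], coords[, 1], "-")
  dy <- outer(pred_coords[, 2], coords[, 2], "-")
  h0 <- sqrt(dx^2 + dy^2)
  c0 <- vg_cov(h0, vg)                     # n_pred x n_obs
  rhs <- cbind(c0, Fp)                     # n_pred x (n + p)
  sol <- rhs %*% t(Ai)                     # n_pred x (n + p)
  w <- sol[, seq_len(n), drop = FALSE]
  lam <- sol[, n + seq_len(p), drop = FALSE]
  pred <- as.vector(w %*% z)
  sigma0 <- vg$nugget + vg$psill
  kvar <- sigma0 - rowSums(w * c0) - rowSums(lam * Fp)
  list(pred = pred, weights = w, var = pmax(kvar, 0))
}

# pseudo-inverse without adding a package dependency for one degenerate path
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Stratified interpolation of footprint-level values to a surface
#'
#' Implements the two-zone interpolation scheme used for boma-density
#' rates: inside protected areas the value is predicted by regression
#' kriging with management unit as the auxiliary variable (a unit-means
#' trend fitted by least squares, residuals kriged with a WLS-fitted
#' exponential variogram), while buffer cells are predicted by universal
#' kriging with a linear spatial drift from the buffer observations alone.
#' The two predictions are masked to their strata and mosaicked.
#'
#' @param points data.frame with `x`, `y`, `value` and `unit` (management
#'   unit name of each footprint centroid).
#' @param cfg the [landscape_config()].
#' @param grid target raster template (e.g. [coarse_grid()]).
#' @return list with `surface` (an [fr_raster()]), the fitted `vg_protected`
#'   and `vg_buffer` variograms, and `weights` diagnostics (row sums of the
#'   kriging weights at every predicted cell, by stratum).
#' @export
krige_surface <- function(points, cfg, grid) {
  is_buf <- points$unit == "buffer"
  if (sum(!is_buf) < 5L || sum(is_buf) < 5L)
    stop("need >= 5 observation points in each stratum (protected / buffer)")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ctr <- fr_cell_center(grid, idx$row, idx$col)
  # padded edge cells can centre past the landscape; clamp for stratum
  # assignment so every cell of the grid is predicted
  cxc <- pmin(pmax(ctr$x, cfg$xmin + 1), cfg$xmin + cfg$width_m - 1)
  cyc <- pmin(pmax(ctr$y, cfg$ymin + 1), cfg$ymin + cfg$height_m - 1)
  cell_unit <- assign_unit(cxc, cyc, cfg$units)
  cell_buf <- cell_unit == "buffer"
  vals <- rep(NA_real_, nrow(idx))
  wsums <- rep(NA_real_, nrow(idx))

  # protected stratum: regression kriging on unit means
  pr <- points[!is_buf, , drop = FALSE]
  unit_means <- tapply(pr$value, pr$unit, mean)
  overall <- mean(pr$value)
  trend_at <- function(u) {
    v <- unit_means[u]
    v[is.na(v)] <- overall   # units without footprints fall back to the mean
    unname(v)
  }
  resid <- pr$value - trend_at(pr$unit)
  vgp <- fit_variogram(empirical_variogram(cbind(pr$x, pr$y), resid))
  sel <- which(!cell_buf)
  if (length(sel)) {
    kp <- krige(cbind(pr$x, pr$y), resid, cbind(ctr$x[sel], ctr$y[sel]), vgp)
    vals[sel] <- trend_at(cell_unit[sel]) + kp$pred
    wsums[sel] <- rowSums(kp$weights)
  }

  # buffer stratum: universal kriging, linear drift
  bf <- points[is_buf, , drop = FALSE]
  vgb <- fit_variogram(empirical_variogram(cbind(bf$x, bf$y), bf$value))
  sel <- which(cell_buf)
  if (length(sel)) {
    kb <- krige(cbind(bf$x, bf$y), bf$value, cbind(ctr$x[sel], ctr$y[sel]),
                vgb, drift = "linear")
    vals[sel] <- kb$pred
    wsums[sel] <- rowSums(kb$weights)
  }
  surface <- grid
  surface$values <- matrix(vals, nr, nc)
  list(surface = surface, vg_protected = vgp, vg_buffer = vgb,
       weight_sums = matrix(wsums, nr, nc))
}
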
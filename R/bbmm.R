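# Brownian bridge movement model: motion-variance estimation by the
# leave-one-out likelihood (odd fixes conditioned on bridges between their
# even neighbours), time-integrated bridge density rasterized on the burn
# grid, Voronoi-fracture reweighting of unbalanced months, and population
# utilization distributions.

#' Estimate Brownian motion variance from a trajectory
#'
#' Maximizes the leave-one-out likelihood: every second fix is treated as an
#' observation of the Brownian bridge spanning its two neighbours, whose
#' mean is the time-linear interpolation and whose variance is
#' `T a (1 - a) sigma2 + ((1-a)^2 + a^2) delta^2` with `a` the time
#' fraction and `delta` the GPS location-error SD. Optimized on the log
#' scale by golden-section search.
#'
#' @param traj data.frame with `t` (seconds), `x`, `y`, ordered in time
#'   (>= 3 fixes).
#' @param loc_error_sd GPS error SD, metres (default 20).
#' @param interval log-scale search interval for `sigma2`.
#' @return estimated motion variance, m^2/s; if the trajectory is degenerate
#'   (no displacement beyond location error) the lower search bound is
#'   returned with a warning.
#' @export
estimate_motion_variance <- function(traj, loc_error_sd = 20,
                                     interval = log(c(1e-6, 1e6))) {
  traj <- traj[order(traj$t), , drop = FALSE]
  n <- nrow(traj)
  if (n < 3L) stop("need at least 3 fixes")
  if (any(diff(traj$t) <= 0)) stop("timestamps must be strictly increasing")
  mid <- seq(2L, n - 1L, by = 2L)
  lo <- mid - 1L; hi <- mid + 1L
  Tt <- traj$t[hi] - traj$t[lo]
  a <- (traj$t[mid] - traj$t[lo]) / Tt
  mux <- traj$x[lo] + a * (traj$x[hi] - traj$x[lo])
  muy <- traj$y[lo] + a * (traj$y[hi] - traj$y[lo])
  err <- ((1 - a)^2 + a^2) * loc_error_sd^2
  nll <- function(ls2) {
    s2 <- Tt * a * (1 - a) * exp(ls2) + err
    -sum(stats::dnorm(traj$x[mid], mux, sqrt(s2), log = TRUE) +
           stats::dnorm(traj$y[mid], muy, sqrt(s2), log = TRUE))
  }
  opt <- stats::optimize(nll, interval = interval)
  if (opt$minimum <= interval[1] + 1e-3) {
    warning("degenerate trajectory: motion variance at lower search bound")
    return(exp(interval[1]))
  }
  exp(opt$minimum)
}

#' Rasterized Brownian bridge utilization distribution
#'
#' Integrates the bridge density over time by midpoint quadrature
#' (`n_quad` points per segment, weighted by segment duration). At each
#' quadrature time the position is Gaussian with isotropic variance, so the
#' mass falling in each cell is an exact product of normal-CDF differences;
#' evaluation is truncated beyond `trunc_sd` standard deviations. The result
#' is normalized to sum to one.
#'
#' @param traj data.frame with `t`, `x`, `y` (one individual, one month).
#' @param sigma2 motion variance, m^2/s.
#' @param grid target [fr_raster()]; must cover the trajectory (an error
#'   otherwise).
#' @param loc_error_sd GPS error SD, metres.
#' @param n_quad quadrature points per segment (default 50).
#' @param trunc_sd evaluation radius in SDs (default 5).
#' @return an [fr_raster()] utilization distribution summing to 1.
#' @export
bbmm_ud <- function(traj, sigma2, grid, loc_error_sd = 20, n_quad = 50L,
                    trunc_sd = 5) {
  traj <- traj[order(traj$t), , drop = FALSE]
  n <- nrow(traj)
  if (n < 2L) stop("need at least 2 fixes for a bridge")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  px <- grid$pixel_size
  xr <- grid$xmin + c(0, nc) * px
  yr <- grid$ymin + c(0, nr) * px
  if (any(traj$x < xr[1] | traj$x > xr[2] | traj$y < yr[1] | traj$y > yr[2]))
    stop("fixes fall outside the grid")
  ud <- matrix(0, nr, nc)
  xb <- grid$xmin + (0:nc) * px   # column breaks
  yb <- grid$ymin + (0:nr) * px   # row breaks
  alphas <- (seq_len(n_quad) - 0.5) / n_quad
  for (s in seq_len(n - 1L)) {
    Tt <- traj$t[s + 1L] - traj$t[s]
    if (Tt <= 0) stop("timestamps must be strictly increasing")
    for (a in alphas) {
      mux <- traj$x[s] + a * (traj$x[s + 1L] - traj$x[s])
      muy <- traj$y[s] + a * (traj$y[s + 1L] - traj$y[s])
      s2 <- Tt * a * (1 - a) * sigma2 +
        ((1 - a)^2 + a^2) * loc_error_sd^2
      sd <- sqrt(s2)
      c0 <- max(1L, findInterval(mux - trunc_sd * sd, xb))
      c1 <- min(nc, 1L + findInterval(mux + trunc_sd * sd, xb,
                                      left.open = TRUE))
      r0 <- max(1L, findInterval(muy - trunc_sd * sd, yb))
      r1 <- min(nr, 1L + findInterval(muy + trunc_sd * sd, yb,
                                      left.open = TRUE))
      if (c1 < c0 || r1 < r0) next
      pxs <- diff(stats::pnorm(xb[c0:(c1 + 1L)], mux, sd))
      pys <- diff(stats::pnorm(yb[r0:(r1 + 1L)], muy, sd))
      ud[r0:r1, c0:c1] <- ud[r0:r1, c0:c1] + (Tt / n_quad) * outer(pys, pxs)
    }
  }
  tot <- sum(ud)
  if (tot <= 0) stop("utilization mass vanished; grid too small?")
  fr_raster(ud / tot, grid$xmin, grid$ymin, px)
}

#' Monthly reweighting factors from pooled fix counts
#'
#' Inverse weighting of unbalanced telemetry sampling: month `m` with `n_m`
#' fixes (pooled across individuals by default) receives weight
#' `min(n) / n_m`, so the sparsest month keeps weight 1 and data-rich months
#' are down-weighted. Months with zero fixes are excluded with a message.
#'
#' @param traj trajectory table with `year`, `month` (and `id`).
#' @param per_individual if TRUE, counts and minima are per individual
#'   rather than pooled.
#' @return named numeric vector of weights (names `"YYYY-MM"`, or
#'   `"id/YYYY-MM"` when per-individual), all in (0, 1].
#' @export
voronoi_fracture_weights <- function(traj, per_individual = FALSE) {
  key <- sprintf("%d-%02d", traj$year, traj$month)
  if (per_individual) key <- paste(traj$id, key, sep = "/")
  counts <- table(key)
  counts <- counts[counts > 0]
  w <- min(counts) / as.numeric(counts)
  names(w) <- names(counts)
  w
}

#' Voronoi fracture assignment of a UD grid to a month's fixes
#'
#' Assigns every grid cell centre to its nearest fix (ties to the
#' lowest-index fix), partitioning the UD support into Voronoi fractures.
#'
#' @param grid an [fr_raster()] (the UD grid).
#' @param fixes data.frame with `x`, `y` of the month's fixes.
#' @return integer matrix of fix indices, same shape as the grid.
#' @export
voronoi_fractures <- function(grid, fixes) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ctr <- fr_cell_center(grid, idx$row, idx$col)
  d2 <- outer(ctr$x, fixes$x, "-")^2 + outer(ctr$y, fixes$y, "-")^2
  matrix(max.col(-d2, ties.method = "first"), nr, nc)
}

#' Fracture masses of a UD
#'
#' Total utilization in each Voronoi fracture; these tile the UD exactly
#' (every cell belongs to one fracture).
#'
#' @param ud an [fr_raster()] UD.
#' @param fractures assignment matrix from [voronoi_fractures()].
#' @return named numeric vector of fracture masses.
#' @export
fracture_masses <- function(ud, fractures) {
  tapply(as.vector(ud$values), as.vector(fractures), sum)
}

#' Monthly population utilization distribution
#'
#' Sums the (reweighted) individual UDs of a month, rescales to total 1,
#' excludes the low-use tail and (by default) renormalizes. Two exclusion
#' conventions are offered: `"cumulative_mass"` drops the lowest-value cells
#' whose cumulative utilization totals the exclusion fraction (so the mass
#' retained before renormalization is 1 minus that fraction);
#' `"value_quantile"` drops cells below the exclusion-fraction quantile of
#' positive cell values.
#'
#' @param uds list of [fr_raster()] individual UDs on a common grid.
#' @param weights numeric vector of per-UD weights (e.g. from
#'   [voronoi_fracture_weights()]); recycled if length 1.
#' @param exclusion exclusion convention.
#' @param exclude_frac tail fraction excluded (default 0.05).
#' @param renormalize rescale to sum 1 after exclusion (default TRUE).
#' @return an [fr_raster()]; the mass retained before renormalization is in
#'   attribute `retained_mass`.
#' @export
population_ud <- function(uds, weights = 1,
                          exclusion = c("cumulative_mass", "value_quantile"),
                          exclude_frac = 0.05, renormalize = TRUE) {
  exclusion <- match.arg(exclusion)
  if (length(uds) == 0L) stop("no individual UDs for this month")
  weights <- rep_len(weights, length(uds))
  acc <- Reduce(`+`, Map(function(u, w) u$values * w, uds, weights))
  acc <- acc / sum(acc)
  v <- as.vector(acc)
  if (exclusion == "cumulative_mass") {
    ord <- order(v)
    drop <- ord[cumsum(v[ord]) <= exclude_frac]
  } else {
    pos <- v[v > 0]
    drop <- which(v < stats::quantile(pos, exclude_frac))
  }
  v[drop] <- 0
  retained <- sum(v)
  if (renormalize && retained > 0) v <- v / retained
  out <- fr_raster(matrix(v, nrow(acc)), uds[[1]]$xmin, uds[[1]]$ymin,
                   uds[[1]]$pixel_size)
  attr(out, "retained_mass") <- retained
  out
}

#' Build monthly population UDs from a trajectory table
#'
#' Fits one motion variance per individual, rasterizes each
#' individual-month UD, reweights months by [voronoi_fracture_weights()]
#' and combines with [population_ud()].
#'
#' @param traj trajectory table from [generate_trajectories()].
#' @param grid target [fr_raster()] covering all fixes.
#' @param loc_error_sd GPS error SD, metres.
#' @param n_quad quadrature points per segment.
#' @param ... passed to [population_ud()].
#' @return named list (`"YYYY-MM"`) of population UDs; per-individual
#'   motion-variance estimates in attribute `sigma2`.
#' @export
monthly_population_uds <- function(traj, grid, loc_error_sd = 20,
                                   n_quad = 30L, ...) {
  sig <- vapply(split(traj, traj$id), function(tr)
    estimate_motion_variance(tr, loc_error_sd), 0)
  w <- voronoi_fracture_weights(traj)
  months <- unique(traj[, c("year", "month")])
  out <- list()
  for (k in seq_len(nrow(months))) {
    lab <- sprintf("%d-%02d", months$year[k], months$month[k])
    sub <- traj[traj$year == months$year[k] & traj$month == months$month[k], ]
    uds <- lapply(split(sub, sub$id), function(tr) {
      if (nrow(tr) < 2L) return(NULL)
      bbmm_ud(tr, sig[[as.character(tr$id[1])]], grid, loc_error_sd, n_quad)
    })
    uds <- Filter(Negate(is.null), uds)
    if (length(uds) == 0L) next
    out[[lab]] <- population_ud(uds, weights = w[[lab]], ...)
  }
  attr(out, "sigma2") <- sig
  out
}

#' Three-month cumulative utilization at a fire
#'
#' Sum of the population-UD values at the fire's centroid cell for the
#' ignition month and the two months before it; missing months make the
#' covariate missing (flagged by a warning).
#'
#' @param fire one event-table row.
#' @param uds named list (`"YYYY-MM"`) of population UDs.
#' @return utilization fraction (0 if the centroid is outside every UD).
#' @export
utilization_3mo <- function(fire, uds) {
  y <- calendar_year_of(fire$ignition_date)
  m <- month_of(fire$ignition_date)
  k <- y * 12L + (m - 1L)
  labs <- sprintf("%d-%02d", (k - 2:0) %/% 12L, (k - 2:0) %% 12L + 1L)
  if (!all(labs %in% names(uds))) {
    warning("missing utilization months; covariate set to missing")
    return(NA_real_)
  }
  sum(vapply(labs, function(l) {
    u <- uds[[l]]
    nr <- nrow(u$values); nc <- ncol(u$values)
    row <- floor((fire$centroid_y - u$ymin) / u$pixel_size) + 1
    col <- floor((fire$centroid_x - u$xmin) / u$pixel_size) + 1
    if (row < 1 || row > nr || col < 1 || col > nc) return(0)
    u$values[row, col]
  }, 0))
}
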
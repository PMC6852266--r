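#' Pearson correlations of annual fire series
#'
#' Correlates each annual characteristic against year, plus the pairwise
#' series of interest (fires vs. area, top-decile size vs. area, top-decile
#' size vs. number of fires). Degrees of freedom follow the `n - 2`
#' convention. Constant series yield undefined correlations and are flagged
#' rather than dropped.
#'
#' @param series annual table from [annual_series()] (>= 3 years).
#' @return data.frame with `pair`, `r`, `r2`, `df`, `p_value`, `flag`.
#' @export
annual_correlations <- function(series) {
  if (nrow(series) < 3L) stop("need at least 3 years")
  pairs <- list(
    c("n_fires", "year"), c("area_burnt_km2", "year"),
    c("median_size_top_decile", "year"), c("median_ignition_day", "year"),
    c("median_tslf_years", "year"), c("median_frp", "year"),
    c("n_fires", "area_burnt_km2"),
    c("median_size_top_decile", "area_burnt_km2"),
    c("median_size_top_decile", "n_fires")
  )
  rows <- lapply(pairs, function(p) {
    x <- series[[p[1]]]; y <- series[[p[2]]]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(pair = paste(p[1], "vs", p[2]), r = NA_real_,
                        r2 = NA_real_, df = length(x) - 2L,
                        p_value = NA_real_, flag = "undefined"))
    }
    ct <- stats::cor.test(x, y)
    data.frame(pair = paste(p[1], "vs", p[2]), r = unname(ct$estimate),
               r2 = unname(ct$estimate)^2, df = unname(ct$parameter),
               p_value = ct$p.value, flag = "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-pixel temporal trend across a yearly raster stack
#'
#' Fits, in every cell, a GLM of the yearly value against `year - base_year`
#' and returns the slope and the predicted baseline at `base_year`. The
#' Gaussian family uses the closed-form least-squares solution applied to
#' all cells at once; the Poisson family (for counts) fits a log-linear GLM
#' per cell. Cells with fewer than 3 non-missing years are flagged missing.
#'
#' @param stack named list (by year) of [fr_raster()] on a common grid.
#' @param family `"gaussian"` or `"poisson"`.
#' @param base_year reference year for the baseline (default: first year).
#' @return list of [fr_raster()]: `slope`, `baseline`, `se`, `n_years`.
#'   For the Poisson family the slope is the log-linear rate and the
#'   baseline is on the response scale.
#' @export
per_pixel_trend <- function(stack, family = c("gaussian", "poisson"),
                            base_year = NULL) {
  family <- match.arg(family)
  years <- as.integer(names(stack))
  if (is.null(base_year)) base_year <- min(years)
  t <- years - base_year
  tmpl <- stack[[1]]
  Y <- vapply(stack, function(r) as.vector(r$values),
              numeric(length(tmpl$values)))            # cells x years
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
  n_ok <- rowSums(!is.na(Y))
  slope <- base <- se <- rep(NA_real_, nrow(Y))
  if (family == "gaussian") {
    for (i in which(n_ok >= 3L)) {
      ok <- !is.na(Y[i, ])
      ti <- t[ok]; yi <- Y[i, ok]
      tb <- mean(ti)
      sxx <- sum((ti - tb)^2)
      b <- sum((ti - tb) * (yi - mean(yi))) / sxx
      a <- mean(yi) - b * tb
      res <- yi - a - b * ti
      s2 <- sum(res^2) / max(length(yi) - 2L, 1L)
      slope[i] <- b
      base[i] <- a
      se[i] <- sqrt(s2 / sxx)
    }
  } else {
    for (i in which(n_ok >= 3L)) {
      ok <- !is.na(Y[i, ])
      fit <- suppressWarnings(stats::glm.fit(
        cbind(1, t[ok]), Y[i, ok], family = stats::poisson()
      ))
      slope[i] <- fit$coefficients[2]
      base[i] <- exp(fit$coefficients[1])
      XtWX <- crossprod(cbind(1, t[ok]) * fit$weights, cbind(1, t[ok]))
      V <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, 2, 2))
      se[i] <- sqrt(V[2, 2])
    }
  }
  shape <- function(v) fr_raster(matrix(v, nrow(tmpl$values)),
                                 tmpl$xmin, tmpl$ymin, tmpl$pixel_size)
  list(slope = shape(slope), baseline = shape(base), se = shape(se),
       n_years = shape(n_ok))
}

#' Likelihood-ratio model reduction by single-term deletions
#'
#' From a full GLM, repeatedly drops the least-supported removable term
#' (respecting marginality: main effects under interactions are not
#' candidates) using log likelihood-ratio tests, until every remaining
#' term is significant at `alpha`. For Gaussian models the statistic is the
#' profile-likelihood ratio `n log(RSS0 / RSS1)`.
#'
#' @param fit a fitted [stats::glm()].
#' @param alpha retention threshold (default 0.05).
#' @return list with `full`, `reduced` (fitted models) and `path`
#'   (data.frame of deletion steps: `term`, `lrt`, `df`, `p_value`,
#'   `dropped`).
#' @export
reduce_by_lrt <- function(fit, alpha = 0.05) {
  full <- fit
  path <- list()
  # refit against the stored model frame so reduction is self-contained
  mf <- stats::model.frame(fit)
  fam <- stats::family(fit)
  repeat {
    scope <- stats::drop.scope(stats::formula(fit))
    if (length(scope) == 0L) break
    ll1 <- stats::logLik(fit)
    cand <- lapply(scope, function(term) {
      new_form <- stats::update(stats::formula(fit),
                                stats::as.formula(paste(". ~ . -", term)))
      red <- stats::glm(new_form, data = mf, family = fam)
      ll0 <- stats::logLik(red)
      lrt <- as.numeric(2 * (ll1 - ll0))
      df <- attr(ll1, "df") - attr(ll0, "df")
      list(term = term, red = red, lrt = lrt, df = df,
           p = stats::pchisq(lrt, df, lower.tail = FALSE))
    })
    ps <- vapply(cand, `[[`, 0, "p")
    k <- which.max(ps)
    dropped <- ps[k] > alpha
    path[[length(path) + 1L]] <- data.frame(
      term = cand[[k]]$term, lrt = cand[[k]]$lrt, df = cand[[k]]$df,
      p_value = ps[k], dropped = dropped
    )
    if (!dropped) break
    fit <- cand[[k]]$red
  }
  list(full = full, reduced = fit,
       path = if (length(path)) do.call(rbind, path)
              else data.frame(term = character(), lrt = numeric(),
                              df = numeric(), p_value = numeric(),
                              dropped = logical()))
}

#' Model of change in burnt area from management and climate drivers
#'
#' Gaussian GLM of the per-cell rate of change in burnt area on the rate of
#' change in boma density, management unit, mean annual rainfall, the rate
#' of change in annual rainfall and the baseline burnt area, with the three
#' interactions of interest (boma rate x rainfall mean, boma rate x
#' baseline, rainfall trend x rainfall mean), then reduced by
#' [reduce_by_lrt()]. Incomplete rows are dropped and counted.
#'
#' @param cells data.frame with columns `area_change`, `boma_rate`, `unit`,
#'   `rain_mean`, `rain_trend`, `baseline`.
#' @param alpha retention threshold for the reduction.
#' @return the [reduce_by_lrt()] result plus `n_used` and `n_dropped`.
#' @export
area_change_model <- function(cells, alpha = 0.05) {
  need <- c("area_change", "boma_rate", "unit", "rain_mean", "rain_trend",
            "baseline")
  keep <- stats::complete.cases(cells[, need])
  d <- cells[keep, , drop = FALSE]
  d$unit <- factor(d$unit)
  form <- area_change ~ boma_rate + unit + rain_mean + rain_trend +
    baseline + boma_rate:rain_mean + boma_rate:baseline +
    rain_trend:rain_mean
  if (nlevels(d$unit) < 2L)
    form <- stats::update(form, . ~ . - unit)
  fit <- stats::glm(form, data = d, family = stats::gaussian())
  # drop aliased terms if the design is rank deficient
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    warning("rank-deficient design; dropping aliased terms: ",
            paste(bad, collapse = ", "))
    keep_terms <- attr(stats::terms(fit), "term.labels")
    for (b in bad) {
      hit <- keep_terms[vapply(keep_terms, function(tm) grepl(tm, b,
                                                              fixed = TRUE),
                               TRUE)]
      keep_terms <- setdiff(keep_terms, hit)
    }
    form <- stats::reformulate(keep_terms, response = "area_change")
    fit <- stats::glm(form, data = d, family = stats::gaussian())
  }
  out <- reduce_by_lrt(fit, alpha)
  out$n_used <- nrow(d)
  out$n_dropped <- sum(!keep)
  out
}

#' Tukey HSD contrasts for a factor in a fitted model
#'
#' All pairwise level contrasts of `factor_name` with familywise adjustment
#' on the studentized-range distribution, via estimated marginal means.
#'
#' @param fit a fitted model retaining `factor_name`.
#' @param factor_name the factor to compare (default `"unit"`).
#' @return data.frame of contrasts with estimates, SEs and adjusted
#'   p-values.
#' @export
tukey_hsd <- function(fit, factor_name = "unit") {
  terms_in <- attr(stats::terms(fit), "term.labels")
  if (!factor_name %in% terms_in)
    stop(sprintf(
      "factor '%s' is not in the model (it may have been removed during reduction)",
      factor_name
    ))
  emm <- emmeans::emmeans(fit, specs = factor_name)
  as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
}

#' Overdispersion check for a Poisson GLM
#'
#' Pearson chi-square divided by residual degrees of freedom, with the
#' one-sided chi-square test of variance exceeding the Poisson mean.
#'
#' @param fit a Poisson [stats::glm()].
#' @param alpha verdict threshold.
#' @return list with `dispersion`, `statistic`, `df`, `p_value`,
#'   `overdispersed`.
#' @export
overdispersion_check <- function(fit, alpha = 0.05) {
  if (stats::family(fit)$family != "poisson")
    stop("overdispersion check expects a Poisson fit")
  X2 <- sum(stats::residuals(fit, type = "pearson")^2)
  df <- stats::df.residual(fit)
  p <- stats::pchisq(X2, df, lower.tail = FALSE)
  list(dispersion = X2 / df, statistic = X2, df = df, p_value = p,
       overdispersed = p < alpha)
}

#' Correlations decomposing change in burnt area
#'
#' Pearson correlations, over coarse-grid cells, between the rate of change
#' in burnt area and (a) the rate of change in fire size and (b) the rate of
#' change in number of fires.
#'
#' @param area_slope,size_slope,count_slope [fr_raster()] trend surfaces on
#'   a common grid.
#' @return data.frame with `pair`, `r`, `r2`, `df`, `p_value`.
#' @export
change_decomposition <- function(area_slope, size_slope, count_slope) {
  a <- as.vector(area_slope$values)
  pairs <- list(size = as.vector(size_slope$values),
                n_fires = as.vector(count_slope$values))
  rows <- lapply(names(pairs), function(nm) {
    b <- pairs[[nm]]
    keep <- !is.na(a) & !is.na(b)
    ct <- stats::cor.test(a[keep], b[keep])
    data.frame(pair = paste("area_change vs", nm, "change"),
               r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
               df = unname(ct$parameter), p_value = ct$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
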
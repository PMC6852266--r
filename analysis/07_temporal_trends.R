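#!/usr/bin/env Rscript
# Stage 7: temporal change -- annual Pearson correlations, per-pixel 6 km
# trend GLMs of burnt area, the reduced model of change in burnt area from
# boma, rainfall and management drivers, overdispersion diagnostics for the
# fire-count trend, and the change decomposition.

source(file.path("analysis", "00_config.R"))
cfgr <- study_config()
cfg <- study_landscape(cfgr)

events <- read.csv(file.path(ana_dir, "fire_events.csv"))
records <- cluster_burned_pixels(
  read.csv(file.path(ana_dir, "burn_records.csv")),
  cfgr$max_gap_days, cfgr$connectivity
)
obs <- read.csv(file.path(ana_dir, "boma_observations.csv"))

ann <- annual_series(events, years = cfgr$years)
corr <- annual_correlations(ann)
write.csv(corr, file.path(ana_dir, "annual_correlations.csv"),
          row.names = FALSE)

ras <- rasterize_characteristic(events, records, cfg, cfgr$cell_km)
area_tr <- per_pixel_trend(ras$area_burnt)
size_tr <- per_pixel_trend(ras$median_size)
count_tr <- per_pixel_trend(ras$n_fires)
decomp <- change_decomposition(area_tr$slope, size_tr$slope, count_tr$slope)
write.csv(decomp, file.path(ana_dir, "change_decomposition.csv"),
          row.names = FALSE)

rain <- generate_rainfall(cfg, cfgr$rain_gradient, cfgr$rain_trend,
                          cfgr$rain_base)
rtr <- annual_rainfall_trend(rain)
bs <- boma_surfaces(fit_local_trends(obs, base_year = cfgr$years[1]),
                    cfg, cfgr$cell_km)

grid <- ras$area_burnt[[1]]
idx <- expand.grid(row = seq_len(nrow(grid$values)),
                   col = seq_len(ncol(grid$values)))
ctr <- fr_cell_center(grid, idx$row, idx$col)
cx <- pmin(pmax(ctr$x, cfg$xmin + 1), cfg$xmin + cfg$width_m - 1)
cy <- pmin(pmax(ctr$y, cfg$ymin + 1), cfg$ymin + cfg$height_m - 1)
cells <- data.frame(
  area_change = as.vector(area_tr$slope$values),
  baseline = as.vector(area_tr$baseline$values),
  boma_rate = bs$rate$values[cbind(idx$row, idx$col)],
  rain_mean = fr_value_at(rtr$mean_annual, cx, cy),
  rain_trend = fr_value_at(rtr$slope, cx, cy),
  unit = assign_unit(ctr$x, ctr$y, cfg$units)
)
acm <- area_change_model(cells, alpha = cfgr$alpha)
write.csv(acm$path, file.path(ana_dir, "area_change_deletion_path.csv"),
          row.names = FALSE)
coefs <- data.frame(term = names(coef(acm$reduced)),
                    estimate = unname(coef(acm$reduced)))
write.csv(coefs, file.path(ana_dir, "area_change_coefficients.csv"),
          row.names = FALSE)

# Poisson trend in total fire counts, with its overdispersion check
cnt <- glm(n_fires ~ I(year - min(year)), data = ann, family = poisson())
od <- overdispersion_check(cnt)

kept <- attr(terms(acm$reduced), "term.labels")
message(sprintf(
  "area-change model: %d/%d cells used, retained terms {%s}; fire-count dispersion %.2f (%s); area~size change r = %.2f, area~count change r = %.2f",
  acm$n_used, acm$n_used + acm$n_dropped, paste(kept, collapse = ", "),
  od$dispersion,
  if (od$overdispersed) "overdispersed" else "no overdispersion",
  decomp$r[1], decomp$r[2]
))
if ("unit" %in% kept) {
  tk <- tukey_hsd(acm$reduced, "unit")
  write.csv(tk, file.path(ana_dir, "tukey_units.csv"), row.names = FALSE)
  message(sprintf("Tukey HSD: %d of %d unit contrasts significant",
                  sum(tk$p.value < cfgr$alpha), nrow(tk)))
}
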
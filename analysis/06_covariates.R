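#!/usr/bin/env Rscript
# Stage 6: per-fire covariates -- monthly and cumulative rainfall at the
# centroid, predicted boma density in the fire year, three-month cumulative
# wildebeest utilization, and management unit; plus the per-pixel annual
# rainfall trend used downstream.

source(file.path("analysis", "00_config.R"))
cfgr <- study_config()
cfg <- study_landscape(cfgr)

events <- read.csv(file.path(ana_dir, "fire_events.csv"))
obs <- read.csv(file.path(ana_dir, "boma_observations.csv"))
traj <- read.csv(file.path(ana_dir, "trajectories.csv"))

rain <- generate_rainfall(cfg, cfgr$rain_gradient, cfgr$rain_trend,
                          cfgr$rain_base)
tr <- fit_local_trends(obs, base_year = cfgr$years[1])
surf <- boma_surfaces(tr, cfg, cfgr$cell_km)
boma_by_year <- lapply(cfgr$years, function(y)
  predict_density(surf, y, base_year = cfgr$years[1]))
names(boma_by_year) <- cfgr$years

pad <- 6 * sqrt(cfgr$sigma2_m * cfgr$fix_interval_hours * 3600)
xr <- range(traj$x) + c(-pad, pad)
yr <- range(traj$y) + c(-pad, pad)
px <- cfgr$pixel_size_m
grid <- fr_raster(matrix(0, ceiling(diff(yr) / px), ceiling(diff(xr) / px)),
                  xmin = xr[1], ymin = yr[1], pixel_size = px)
uds <- monthly_population_uds(traj, grid, cfgr$loc_error_sd)

cv <- build_fire_covariates(events, rain = rain,
                            cumulative_mode = cfgr$cumulative_mode,
                            boma_by_year = boma_by_year, uds = uds)
write.csv(cv, file.path(ana_dir, "covariates.csv"), row.names = FALSE)

rtr <- annual_rainfall_trend(rain)
write.csv(fr_as_df(rtr$slope, drop_na = FALSE),
          file.path(ana_dir, "rainfall_trend.csv"), row.names = FALSE)

message(sprintf(
  "covariates for %d fires: monthly rain %.0f-%.0f mm, cumulative rain %.0f-%.0f mm (%d fires predate the window), mean annual rainfall trend %.1f mm/yr2 (planted %.1f)",
  nrow(cv), min(cv$monthly_rain), max(cv$monthly_rain),
  min(cv$cumulative_rain, na.rm = TRUE),
  max(cv$cumulative_rain, na.rm = TRUE), sum(is.na(cv$cumulative_rain)),
  mean(rtr$slope$values), cfgr$rain_trend
))
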
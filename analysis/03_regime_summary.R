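#!/usr/bin/env Rscript
# Stage 3: descriptive fire-regime surfaces and series -- annual totals and
# medians, per-management-unit summaries, 6 km rasterizations and the
# never-burnt extent.

source(file.path("analysis", "00_config.R"))
cfgr <- study_config()
cfg <- study_landscape(cfgr)

records <- read.csv(file.path(ana_dir, "burn_records.csv"))
events <- read.csv(file.path(ana_dir, "fire_events.csv"))
fl_records <- cluster_burned_pixels(records, cfgr$max_gap_days,
                                    cfgr$connectivity)

ann <- annual_series(events, years = cfgr$years)
us <- unit_summary(events, fl_records, cfg)
unb <- unburnt_extent(fl_records, cfg)

write.csv(ann, file.path(ana_dir, "annual_series.csv"), row.names = FALSE)
write.csv(us, file.path(ana_dir, "unit_summary.csv"), row.names = FALSE)

ras <- rasterize_characteristic(events, fl_records, cfg, cfgr$cell_km)
area6 <- do.call(rbind, lapply(names(ras$area_burnt), function(y) {
  df <- fr_as_df(ras$area_burnt[[y]], drop_na = FALSE)
  df$year <- as.integer(y)
  df
}))
write.csv(area6, file.path(ana_dir, "area_burnt_6km.csv"), row.names = FALSE)

message(sprintf(
  "annual area burnt %.0f-%.0f km2 (median %.0f, %.1f%% of the region); top-decile share %.0f-%.0f%%; %.0f km2 (%.1f%%) never burnt",
  min(ann$area_burnt_km2), max(ann$area_burnt_km2),
  median(ann$area_burnt_km2),
  100 * median(ann$area_burnt_km2) /
    (cfg$grid_nrows * cfg$grid_ncols * (cfg$pixel_size_m / 1000)^2),
  100 * min(ann$top_decile_share, na.rm = TRUE),
  100 * max(ann$top_decile_share, na.rm = TRUE),
  unb$km2, 100 * unb$fraction
))
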
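#!/usr/bin/env Rscript
# Stage 4: livestock-pressure surfaces -- per-footprint Poisson trends in
# boma counts, stratified kriging of rates and baselines to 6 km, yearly
# predicted density, and a hold-out verification against the generator's
# truth.

source(file.path("analysis", "00_config.R"))
cfgr <- study_config()
cfg <- study_landscape(cfgr)

obs <- read.csv(file.path(ana_dir, "boma_observations.csv"))
tr <- fit_local_trends(obs, base_year = cfgr$years[1])
write.csv(tr, file.path(ana_dir, "boma_trends.csv"), row.names = FALSE)

surf <- boma_surfaces(tr, cfg, cfgr$cell_km)
write.csv(fr_as_df(surf$rate, drop_na = FALSE),
          file.path(ana_dir, "boma_rate_6km.csv"), row.names = FALSE)
for (y in c(cfgr$years[1], cfgr$years[length(cfgr$years)])) {
  d <- predict_density(surf, y, base_year = cfgr$years[1])
  write.csv(fr_as_df(d, drop_na = FALSE),
            file.path(ana_dir, sprintf("boma_density_%d.csv", y)),
            row.names = FALSE)
}

truth <- attr(generate_boma_observations(cfg, cfgr$boma_slope,
                                         cfgr$n_footprints), "truth")
base_by_unit <- tapply(truth$base, truth$unit, mean)
actual_fun <- function(x, y, year) {
  u <- assign_unit(x, y, cfg$units)
  b <- if (is.na(u) || !u %in% names(base_by_unit)) mean(truth$base)
       else base_by_unit[[u]]
  max(0, b + cfgr$boma_slope * (year - cfgr$years[1]))
}
surf_fine <- boma_surfaces(tr, cfg, cell_km = 2)
rep <- holdout_verification(surf_fine, obs, cfg, actual_fun,
                            year = max(cfgr$years),
                            fraction = cfgr$holdout_fraction,
                            seed = cfgr$seed)

ok <- tr$flag == "ok" & !is.na(tr$rate)
message(sprintf(
  "mean recovered boma rate %.3f (planted %.3f) over %d footprints; hold-out r = %.2f (p = %.3g, n = %d), predicted:actual ratio %.1f",
  mean(tr$rate[ok]), cfgr$boma_slope, sum(ok),
  rep$r, rep$p_value, rep$n_holdout, rep$ratio
))
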
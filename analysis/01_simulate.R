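#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system -- a 14-year burn history
# with known fire labels, active-fire detections at 21% coverage, bimodal
# rainfall with an east-west gradient and a positive trend, boma counts in
# overlapping image footprints, and GPS trajectories.

source(file.path("analysis", "00_config.R"))
cfgr <- study_config()
cfg <- study_landscape(cfgr)

burns <- generate_burn_history(cfg, cfgr$n_fires_per_year,
                               cfgr$mean_fire_pixels)
det <- generate_active_fires(burns, cfg, cfgr$detection_prob,
                             cfgr$frp_scale)
bomas <- generate_boma_observations(cfg, cfgr$boma_slope, cfgr$n_footprints)
traj <- generate_trajectories(cfg, cfgr$n_individuals,
                              months = data.frame(year = cfgr$years[1],
                                                  month = 5:9),
                              sigma2_m = cfgr$sigma2_m)

write.csv(burns$records, file.path(ana_dir, "burn_records.csv"),
          row.names = FALSE)
write.csv(det, file.path(ana_dir, "detections.csv"), row.names = FALSE)
write.csv(bomas, file.path(ana_dir, "boma_observations.csv"),
          row.names = FALSE)
write.csv(traj, file.path(ana_dir, "trajectories.csv"), row.names = FALSE)
write_run_config(cfgr, file.path(ana_dir, "config.yaml"))

message(sprintf(
  "simulated %d burned pixels in %d true fires over %d years; %d detections (%.0f%% of fires); %d boma observations; %d GPS fixes",
  nrow(burns$records), length(unique(burns$records$true_event)),
  length(cfgr$years), nrow(det),
  100 * attr(det, "detection_prob"), nrow(bomas), nrow(traj)
))
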
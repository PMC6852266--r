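# Shared setup for the numbered analysis scripts: one study configuration,
# sourced by every stage so all scripts work on the same synthetic
# landscape. Outputs accumulate under results/analysis/.

library(fireregime)

ana_dir <- file.path("results", "analysis")
dir.create(ana_dir, recursive = TRUE, showWarnings = FALSE)

# a 48 x 48 km landscape: 6 km analysis cells tile it exactly (8 x 8), and
# 40 fires a year give the temporal model a usable cell count
study_config <- function() {
  run_config(out_dir = ana_dir, seed = 2001L,
             grid_nrows = 96L, grid_ncols = 96L,
             n_fires_per_year = 40L, mean_fire_pixels = 8L,
             n_footprints = 120L)
}

study_landscape <- function(cfg = study_config()) {
  landscape_config(cfg$grid_nrows, cfg$grid_ncols, cfg$pixel_size_m,
                   years = cfg$years, seed = cfg$seed,
                   buffer_pixels = cfg$buffer_pixels)
}
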
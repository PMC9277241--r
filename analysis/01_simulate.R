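#!/usr/bin/env Rscript
# Stage 1 — simulate a synthetic shearwater colony.
#
# Generates the study's raw inputs from one root seed: daily Secchi-disc
# depth, hourly cloud and static bathymetry grids; 5-min GPS tracks driven
# by the 3-state movement truth (transitions depending on local Secchi
# depth); and 0.5 Hz depth traces with daylight-gated, bout-structured
# dives. Everything is written as plain CSV under results/data/ together
# with the ground truth (true states, true dive list) used downstream for
# recovery checks.

library(turbidive)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)
write_sim_csvs(sim, "results/data")
saveRDS(cfg, "results/data/config.rds")

pd <- with(sim$dives, tapply(max_depth_m, list(bird_id, as.Date(start, tz = "UTC")), length))
cat(sprintf("Simulated %d birds x %d-day trips: %d fixes, %d dives\n",
            cfg$n_birds, cfg$days_per_trip, nrow(sim$gps), nrow(sim$dives)))
cat(sprintf("Dives per bird-day: %.1f +/- %.1f (field studies report ~67 +/- 33)\n",
            mean(pd, na.rm = TRUE), sd(pd, na.rm = TRUE)))
cat(sprintf("Secchi field: mean %.2f m, sd %.2f m (target 7.5 / 2.6)\n",
            mean(sim$env$zsd$values), sd(sim$env$zsd$values)))
cat(sprintf("Dives below civil twilight at their fix: %d (daylight gate)\n",
            sum(sim$fix_table$n_dives[sim$fix_table$solar_deg < CIVIL_TWILIGHT_DEG])))
cat("Wrote results/data/{gps,tdr,zsd,cloud,bathymetry,truth_*}.csv\n")
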
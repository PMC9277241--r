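#!/usr/bin/env Rscript
# Stage 2 — regularize tracks and segment foraging trips.
#
# Reads the raw GPS table, interpolates to exact 5-min fixes (splitting at
# gaps > 1 h), extracts foraging trips (>= 6 h spent > 5 km from the
# colony, colony-radius points removed), and derives step lengths and
# turning angles — the observation series of the movement model.

library(turbidive)

cfg <- readRDS("results/data/config.rds")
gps <- read.csv("results/data/gps.csv", stringsAsFactors = FALSE)
gps$timestamp <- as.POSIXct(gps$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")

segments <- interpolate_track(gps, interval_s = cfg$fix_interval_s)
trips <- segment_trips(segments, cfg$colony)
obs <- hmm_obs_table(trips)

dir.create("results/intermediates", showWarnings = FALSE, recursive = TRUE)
tr_out <- trips
tr_out$start <- format(tr_out$start, "%Y-%m-%dT%H:%M:%SZ")
tr_out$end <- format(tr_out$end, "%Y-%m-%dT%H:%M:%SZ")
write.csv(tr_out, "results/intermediates/trips.csv", row.names = FALSE)
obs_out <- obs
obs_out$timestamp <- format(obs_out$timestamp, "%Y-%m-%dT%H:%M:%SZ")
write.csv(obs_out, "results/intermediates/track_obs.csv", row.names = FALSE)

cat(sprintf("%d raw fixes -> %d track segments -> %d foraging trips\n",
            nrow(gps), length(segments), nrow(trips)))
cat(sprintf("Trip durations %.1f-%.1f h; max ranges %.1f-%.1f km\n",
            min(trips$duration_h), max(trips$duration_h),
            min(trips$max_range_km), max(trips$max_range_km)))
cat(sprintf("Observation series: %d points (steps %.2f km median)\n",
            nrow(obs), median(obs$step_km, na.rm = TRUE)))
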
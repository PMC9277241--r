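#!/usr/bin/env Rscript
# Stage 4 — annotate track points with environmental covariates.
#
# Adds Secchi-disc depth (nearest 4 km cell, matching calendar day), cloud
# cover (bilinear in space, nearest hour), static water depth, solar
# elevation and time of day to every track observation, and joins the
# per-fix dive counts from stage 3. Rows whose covariates fall outside the
# grids are flagged and counted, never silently dropped here.

library(turbidive)

obs <- read.csv("results/intermediates/track_obs.csv", stringsAsFactors = FALSE)
obs$timestamp <- as.POSIXct(obs$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
env <- list(zsd = read_field_csv("results/data/zsd.csv", "zsd"),
            cloud = read_field_csv("results/data/cloud.csv", "cloud"),
            bathymetry = read_field_csv("results/data/bathymetry.csv",
                                        "bathymetry"))
counts <- read.csv("results/intermediates/fix_counts.csv",
                   stringsAsFactors = FALSE)

fx <- annotate_points(obs, env)
fx$n_dives <- counts$n_dives[match(paste(fx$bird_id, format(fx$timestamp,
                                         "%Y-%m-%dT%H:%M:%SZ")),
                                   paste(counts$bird_id, counts$timestamp))]

out <- fx
out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ")
write.csv(out, "results/intermediates/fix_table.csv", row.names = FALSE)

cat(sprintf("Annotated %d track points (%d with missing covariates)\n",
            nrow(fx), sum(fx$env_missing)))
cat(sprintf("Secchi depth encountered: %.1f +/- %.1f m; cloud %.0f%% median\n",
            mean(fx$zsd_m, na.rm = TRUE), sd(fx$zsd_m, na.rm = TRUE),
            median(fx$cloud_pct, na.rm = TRUE)))
cat(sprintf("%.1f%% of points in daylight (solar angle >= %d deg)\n",
            100 * mean(fx$solar_deg >= CIVIL_TWILIGHT_DEG), CIVIL_TWILIGHT_DEG))
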
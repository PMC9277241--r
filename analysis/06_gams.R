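#!/usr/bin/env Rscript
# Stage 6 — penalized-spline models of dive rate and dive depth.
#
# Dive rate: negative-binomial (log link) count per 5-min fix with a
# solar x Secchi tensor product, shrinkage spline of cloud, cyclic time of
# day, a random bird intercept, and an AR(1) working correlation along
# trips; goodness of fit as deviance explained and presence/absence AUC.
# Dive depth: Gaussian model of the bout maximum depth adding water depth
# and the decoded behavioural state (contrasts against rest).

library(turbidive)

fx <- read.csv("results/intermediates/fix_table.csv", stringsAsFactors = FALSE)
fx <- fx[!fx$env_missing & !is.na(fx$n_dives), ]
dec <- read.csv("results/fit/decoded_states.csv", stringsAsFactors = FALSE)
bouts <- read.csv("results/intermediates/bouts.csv", stringsAsFactors = FALSE)

rate <- fit_dive_rate_model(fx)
cat("Dive rate (negative binomial, log link):\n")
print(rate)
cat(sprintf("AUC for dive presence: %.2f\n", rate$auc))

## bout table: covariates and decoded state of the bout's nearest fix
key <- paste(fx$bird_id, fx$timestamp)
bi <- vapply(seq_len(nrow(bouts)), function(j) {
  cand <- which(fx$bird_id == bouts$bird_id[j])
  cand[which.min(abs(as.numeric(as.POSIXct(fx$timestamp[cand],
                       format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) -
                     as.numeric(as.POSIXct(bouts$start[j],
                       format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))))]
}, 1L)
bt <- cbind(bouts, fx[bi, c("solar_deg", "zsd_m", "cloud_pct",
                            "time_of_day_h", "water_depth_m")])
bt$hmm_state <- dec$state_zsd[match(key[bi], paste(dec$bird_id, dec$timestamp))]

depth <- fit_dive_depth_model(bt)
cat("\nDive depth (Gaussian, bout maxima):\n")
print(depth)
print(depth$state_contrasts)

dir.create("results/fit", showWarnings = FALSE, recursive = TRUE)
write.csv(rate$table, "results/fit/rate_model_terms.csv", row.names = FALSE)
write.csv(depth$table, "results/fit/depth_model_terms.csv", row.names = FALSE)
write.csv(depth$state_contrasts, "results/fit/depth_state_contrasts.csv",
          row.names = FALSE)
surf <- tensor_surface(rate, range(fx$solar_deg),
                       quantile(fx$zsd_m, c(0.02, 0.98)), n = 20)
write.csv(surf, "results/fit/rate_tensor_surface.csv", row.names = FALSE)
jsonlite::write_json(
  list(rate_deviance_explained = rate$dev_expl, rate_auc = rate$auc,
       rate_rho = rate$rho, rate_theta = rate$theta,
       depth_deviance_explained = depth$dev_expl,
       rate_selected_against = rate$selected_against,
       depth_selected_against = depth$selected_against),
  "results/fit/gam_summaries.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/fit/{rate,depth}_model_terms.csv and gam_summaries.json\n")
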
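#!/usr/bin/env Rscript
# Stage 3 — detect dives, estimate the bout-ending criterion, group bouts.
#
# Dives are maximal runs of 0.5 Hz depth samples > 1 m. Surface intervals
# between dives are pooled across birds and the fast/slow two-process model
# is fitted to the binned log frequencies by weighted nonlinear least
# squares; the criterion (where the two processes intersect) then groups
# dives into bouts, and dives are attached to their nearest track point.

library(turbidive)

tdr <- read.csv("results/data/tdr.csv", stringsAsFactors = FALSE)
tdr$timestamp <- as.POSIXct(tdr$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
obs <- read.csv("results/intermediates/track_obs.csv", stringsAsFactors = FALSE)
obs$timestamp <- as.POSIXct(obs$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")

dives <- do.call(rbind, lapply(split(tdr, tdr$bird_id), detect_dives))
iv <- unlist(lapply(split(dives, dives$bird_id), function(d) {
  d <- d[order(d$start), ]
  as.numeric(d$start[-1]) - as.numeric(d$end[-nrow(d)])
}), use.names = FALSE)
bec <- fit_bec(iv)
bec_s <- if (bec$converged) bec$bec_s else 180
cat(sprintf("Detected %d dives; %d surface intervals\n", nrow(dives), length(iv)))
print(bec)

bouts <- assign_bouts(dives, bec_s)
att <- suppressWarnings(attach_dives(bouts$dives, list(obs)))

fmt <- function(df) {
  for (cl in names(df)) if (inherits(df[[cl]], "POSIXct")) {
    df[[cl]] <- format(df[[cl]], "%Y-%m-%dT%H:%M:%SZ")
  }
  df
}
write.csv(fmt(att$dives), "results/intermediates/dives.csv", row.names = FALSE)
write.csv(fmt(bouts$bouts), "results/intermediates/bouts.csv", row.names = FALSE)
write.csv(fmt(att$fix_counts), "results/intermediates/fix_counts.csv",
          row.names = FALSE)

cat(sprintf("Bout-ending criterion %.0f s -> %d bouts (%.1f dives/bout)\n",
            bec_s, nrow(bouts$bouts), nrow(dives) / nrow(bouts$bouts)))
cat(sprintf("%d of %d dives assigned to a track point\n",
            sum(!is.na(att$dives$assigned_fix)), nrow(dives)))
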
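#!/usr/bin/env Rscript
# Stage 7 — one-shot reproduction and consolidated report.
#
# Re-runs the whole chain (simulate -> preprocess -> dives -> annotate ->
# HMM -> models) through the orchestrated pipeline with the same seed and
# writes the consolidated report (JSON + markdown) under results/run/.
# Because every stage draws from named substreams of the root seed, the
# stage-by-stage scripts (01-06) and this single call agree.

library(turbidive)

cfg <- readRDS("results/data/config.rds")
run <- suppressWarnings(run_all(cfg, out_dir = "results/run",
                                write_data = FALSE))
print(run)
cat("\nAttrition log:\n")
print(run$report$attrition)
cat("\nFull report: results/run/report/report.md\n")
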
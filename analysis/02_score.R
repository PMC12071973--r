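#!/usr/bin/env Rscript

# Stage 2: score every simulated patient on the three matrix tracks.
#
# Reads results/sim/{patients,events}.csv, validates and attaches the events,
# evaluates the SWA, PBA and combined ladders per patient, and writes
# results/scores.csv with per-criterion audit flags.

suppressPackageStartupMessages(library(carematrix))

scores <- run_score("results/sim/patients.csv", "results/sim/events.csv",
                    "results/scores.csv")

for (col in c("swa_level", "pba_level", "combined_level")) {
  tab <- table(factor(scores[[col]], levels = 1:5))
  cat(sprintf("%-14s level counts 1..5: %s\n", col,
              paste(as.integer(tab), collapse = " / ")))
}
cat("wrote: results/scores.csv\n")
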
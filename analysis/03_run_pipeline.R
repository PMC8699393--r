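#!/usr/bin/env Rscript
# Stage 3: run the full analysis over the simulated track tables written by
# stage 2 (read back from disk, so the I/O layer is exercised end to end)
# and write the report tables: per-experiment correlations by generation
# grouping, sister-pair correlations, the dividing/non-dividing comparison,
# and persistence indices.

suppressMessages(library(lineagepump))

if (!file.exists("results/simulated/tracks.csv"))
  stop("run analysis/02_simulate_cocultures.R first")
forests <- read_track_table("results/simulated/tracks.csv")
cat("read", length(forests), "experiments\n")

report <- run_analysis(forests)
print(report)
write_report(report, "results/pipeline")
cat("wrote results/pipeline/{correlations,mitosis,summary,sister_correlations}.csv and persistence.json\n")
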
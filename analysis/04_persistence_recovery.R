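#!/usr/bin/env Rscript
# Stage 4: a small recovery study of the persistence index.  Simulated
# batches with every phenotype driver resetting at division should score a
# low area persistence index; batches with inherited drivers should score
# high; with the division-uptake link on, dividing cells should show a
# higher median Fa/day than non-dividing cells.  Five batch pairs here keep
# the script quick; the full 20-batch version runs in the test suite.
#
# Usage: Rscript analysis/04_persistence_recovery.R [seed]

suppressMessages(library(lineagepump))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

n_batches <- 5L
rows <- list()
for (b in seq_len(n_batches)) {
  for (sw in c("reset", "inherit")) {
    switches <- list(area = sw, circularity = sw, velocity = sw)
    batch <- simulate_experiment_batch(seed = seed + 100L * b +
                                         (sw == "inherit") * 50L,
                                       persistence = switches)
    rep <- run_analysis(lapply(batch, `[[`, "forest"))
    rows[[paste(b, sw)]] <- data.frame(
      batch = b, switch = sw,
      area_index = rep$persistence$area$index,
      circularity_index = rep$persistence$circularity$index,
      velocity_index = rep$persistence$velocity$index,
      mitosis_index = rep$persistence$mitosis$index,
      median_pFa = median(rep$mitosis$pFa))
  }
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/persistence_recovery.csv", row.names = FALSE)

cat("area persistence index by driver switch (5 batches of 7 experiments):\n")
for (sw in c("reset", "inherit"))
  cat(sprintf("  %-7s: %s\n", sw,
              paste(sprintf("%.2f", out$area_index[out$switch == sw]),
                    collapse = " ")))
cat(sprintf("median pFa > 1 in %d/%d reset batches\n",
            sum(out$median_pFa[out$switch == "reset"] > 1), n_batches))
cat("wrote results/persistence_recovery.csv\n")
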
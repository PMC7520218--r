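#!/usr/bin/env Rscript
# Step 4: tally the scale-dependence classification — how often does the
# management response reverse between the 1 m^2 subplot scale and the pooled
# site scale, and how often is it confined to a single scale? Writes
# results/quadrant_summary.csv.

suppressPackageStartupMessages(library(scalediv))

cls <- read.csv("results/pipeline/classification.csv")
rows <- list()
for (grp in unique(cls$taxon_group)) {
  for (m in unique(cls$metric)) {
    s <- summarize_quadrants(cls[cls$taxon_group == grp, ], metric = m)
    rows[[paste(grp, m)]] <- data.frame(
      taxon_group = grp, metric = m, n_cases = s$n_cases,
      t(s$counts), reversal_fraction = s$reversal_fraction)
  }
}
summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
write.csv(summary, "results/quadrant_summary.csv", row.names = FALSE)
print(summary, digits = 3, row.names = FALSE)

overall <- summarize_quadrants(cls)
cat(sprintf("\n%d site x group x metric cases; %.0f%% qualitative reversals, %.0f%% with no significant response\n",
            overall$n_cases, 100 * overall$reversal_fraction,
            100 * mean(cls$category == "none")))
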
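#!/usr/bin/env Rscript
# Effective isomerization barriers.
#
# Builds the directional barrier summaries from the packaged gas and water
# barrier tables, selects each compound's minimum free-energy barrier
# (dG_eff) with its syn/anti argmin, and writes
# results/effective_barriers.tsv.

suppressPackageStartupMessages(library(amidescan))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (n in c(11, 12)) {
  phase <- if (n == 11) "gas" else "water"
  printed <- amide_table(n)
  for (s in barrier_summaries(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      compound = s$compound, phase = phase,
      dg_eff = s$dg_eff, argmin = s$argmin,
      dg_eff_printed = printed$dg_eff[printed$compound == s$compound])
  }
}
barriers <- do.call(rbind, rows)
write.table(barriers, "results/effective_barriers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("dG_eff reproduced for all %d compound/phase entries: %s\n",
            nrow(barriers),
            all(barriers$dg_eff == barriers$dg_eff_printed)))
gas <- barriers[barriers$phase == "gas", ]
water <- barriers[barriers$phase == "water", ]
cat(sprintf("Gas-phase dG_eff spread: %.2f - %.2f kcal/mol (bulk has little effect).\n",
            min(gas$dg_eff), max(gas$dg_eff)))
cat(sprintf("Water-phase dG_eff spread: %.2f - %.2f kcal/mol (up to ~5 kcal/mol above GGMe).\n",
            min(water$dg_eff), max(water$dg_eff)))
syn_rows <- barriers[grepl("^syn", barriers$argmin), ]
if (nrow(syn_rows) > 0) {
  cat("Compounds whose cheapest path is a syn barrier:\n")
  print(syn_rows[, c("compound", "phase", "dg_eff", "argmin")], row.names = FALSE)
}
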
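#!/usr/bin/env Rscript
# Validation of the relaxed-coordinate-scan driver.
#
# Runs the three-round directional scan protocol over a seeded battery of
# two-well Fourier torsion potentials and compares every located barrier
# (position and height, both directions from both wells) against the
# 0.001-degree dense-grid ground truth. Writes results/scan_validation.tsv.

suppressPackageStartupMessages(library(amidescan))
dir.create("results", showWarnings = FALSE)

random_two_well <- function(i) {
  set.seed(1000 + i)
  v2 <- runif(1, 8, 20)
  v1 <- runif(1, -0.3, 0.3) * v2
  v3 <- runif(1, -0.12, 0.12) * v2
  g1 <- runif(1, -20, 20); g2 <- runif(1, -8, 8); g3 <- runif(1, -20, 20)
  make_potential(data.frame(k = 1:3, v = c(v1, v2, v3), gamma = c(g1, g2, g3)),
                 name = sprintf("battery-%02d", i))
}

rows <- list()
for (i in 1:20) {
  b <- random_two_well(i)
  gt <- ground_truth(b)
  for (iso in c("trans", "cis")) {
    start <- if (iso == "trans") gt$omega_min_trans else gt$omega_min_cis
    gcol <- if (iso == "trans") "direction_from_trans" else "direction_from_cis"
    for (dd in c("+", "-")) {
      p <- run_rcs(b, start, dd)
      e <- find_ebg(p)
      ref <- gt$barriers[gt$barriers[[gcol]] == dd, ]
      href <- if (iso == "trans") ref$height_vs_trans else ref$height_vs_cis
      rows[[length(rows) + 1L]] <- data.frame(
        potential = b$name, start_isomer = iso, direction = dd,
        omega_star = e$omega_star, omega_oracle = ref$omega_star,
        height = e$e_star, height_oracle = href,
        type = e$type, n_eval = p$n_eval)
    }
  }
}
scan <- do.call(rbind, rows)
scan$omega_err <- pmin(abs(scan$omega_star - scan$omega_oracle),
                       360 - abs(scan$omega_star - scan$omega_oracle))
scan$height_err <- abs(scan$height - scan$height_oracle)
write.table(scan, "results/scan_validation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d directional scans over %d potentials.\n", nrow(scan), 20))
cat(sprintf("Barrier position error: max %.4f degrees (final step 0.125).\n",
            max(scan$omega_err)))
cat(sprintf("Barrier height error:   max %.2e kcal/mol (tolerance 0.01).\n",
            max(scan$height_err)))
cat(sprintf("Backend evaluations per scan: %d - %d (schedule bound ~116).\n",
            min(scan$n_eval), max(scan$n_eval)))
cat(sprintf("Trans-start barriers classified syn: %d/40; cis-start anti: %d/40.\n",
            sum(scan$type == "syn" & scan$start_isomer == "trans"),
            sum(scan$type == "anti" & scan$start_isomer == "cis")))
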
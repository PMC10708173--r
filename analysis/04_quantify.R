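#!/usr/bin/env Rscript
# Stage 4 — validate the ranking by quantifying a target gene under
# contrasting normalization schemes.
#
# First checks primer-style amplification efficiencies by standard-curve
# fitting on simulated dilution series, then expresses a planted
# treatment-responsive target relative to the mock (CK) control,
# normalized by each top-3 reference singly, the three combined, and the
# two bottom-ranked references — the consequence-of-choice contrast.
# Requires analysis/01_simulate.R and analysis/03_stability.R.

suppressPackageStartupMessages(library(refstab))

## standard curves at the edges of the plausible efficiency window
effs <- c(1.9108, 2.0, 2.0805)
fits <- lapply(effs, function(E) {
  fit_standard_curve(simulate_dilution_series(E, n_points = 6,
                                              noise_sd = 0.05,
                                              seed = round(1000 * E)))
})
cat("standard curves (fitted from noisy 6-point series):\n")
for (f in fits) {
  cat(sprintf("  slope %.4f  ->  efficiency %.2f%%  (R^2 = %.4f)\n",
              f$slope, f$efficiency_pct, f$r_squared))
}

cqtab <- read_cq_table("results/data/cq.csv")
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)
target <- truth$unstable[1]

fc_all <- list(); div_all <- list()
for (tissue in c("leaf", "shoot", "root")) {
  rep <- read_stability_report(sprintf("results/stability_%s.tsv", tissue))
  ranking <- setdiff(rep$gene, target)
  top3 <- ranking[1:3]; bottom2 <- tail(ranking, 2)
  schemes <- c(setNames(list(top3), paste(top3, collapse = "+")),
               setNames(as.list(top3), top3),
               setNames(as.list(bottom2), bottom2))
  cmp <- compare_normalizations(cqtab, target, schemes, tissue)
  cmp$divergence$tissue <- tissue
  fc_all[[tissue]] <- cmp$fold_changes
  div_all[[tissue]] <- cmp$divergence

  s <- summarize_fold_changes(
    cmp$fold_changes[cmp$fold_changes$scheme == names(schemes)[1], ])
  cat(sprintf("\n%s: %s relative to CK, normalized by %s\n", tissue,
              target, names(schemes)[1]))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s mean FC %6.2f  (SD of log2 FC %.2f, n = %d)\n",
                s$treatment[i], s$mean_fc[i], s$sd_log2[i], s$n[i]))
  }
  worst <- cmp$divergence[which.max(cmp$divergence$max_abs_log2_diff), ]
  cat(sprintf("  largest scheme divergence: %s, %.2f log2 units vs %s\n",
              worst$scheme, worst$max_abs_log2_diff,
              worst$reference_scheme))
}

write_fold_change(do.call(rbind, fc_all), "results/fold_change.tsv")
write.table(do.call(rbind, div_all), "results/divergence.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nwrote results/fold_change.tsv, results/divergence.tsv\n")
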
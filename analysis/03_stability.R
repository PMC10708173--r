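#!/usr/bin/env Rscript
# Stage 3 — rank candidate stability per tissue with four algorithms.
#
# geNorm (pairwise-variation M), NormFinder (inter/intra-group variance
# model), BestKeeper (raw-Cq SD), and comparative dCt, combined into a
# geometric-mean comprehensive rank.  Each tissue is ranked on its
# pooled samples (both varieties, all treatments), the way the per-tissue
# panels are read.  Requires analysis/01_simulate.R.

suppressPackageStartupMessages(library(refstab))

cqtab <- read_cq_table("results/data/cq.csv")
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)

for (tissue in c("leaf", "shoot", "root")) {
  rep <- rank_stability(cqtab, tissue = tissue)
  write_stability_report(rep, sprintf("results/stability_%s.tsv", tissue))
  top3 <- rep$gene[rep$final_rank <= 3]
  cat(sprintf("%-5s top 3 (comprehensive): %s  | planted stable recovered: %s\n",
              tissue, paste(top3, collapse = ", "),
              setequal(top3, truth$stable)))
  v <- genorm_pairwise_v(
    to_quantities(aggregate_tech_reps(cqtab), tissue),
    rep$gene[order(rep$genorm_rank)])
  cat(sprintf("      geNorm V2/3 = %.3f (< 0.15 cutoff: two references suffice: %s)\n",
              v[["V2/3"]], v[["V2/3"]] < 0.15))
}
cat("wrote results/stability_<tissue>.tsv\n")
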
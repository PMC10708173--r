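#!/usr/bin/env Rscript
# Stage 1 — generate the study's synthetic datasets.
#
# Emulates the two data sources the analysis runs on: six multi-condition
# RNA-seq FPKM datasets (candidate mining substrate) and one RT-qPCR Cq
# experiment over 2 varieties x 3 tissues x 3 treatments with 3
# biological and 3 technical replicates (stability/validation
# substrate), both with planted ground truth.  Run from the repository
# root: Rscript analysis/01_simulate.R

suppressPackageStartupMessages(library(refstab))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
design <- simulation_design(seed = 20231123)

fp <- simulate_fpkm_panel(design)
write_expression_panel(fp$panel, file.path(out, "expression.tsv"),
                       file.path(out, "samples.csv"))

cq <- simulate_cq_experiment(design)
write_cq_table(cq$table, file.path(out, "cq.csv"))

jsonlite::write_json(
  list(stable = fp$truth$stable_gene_ids,
       unstable = fp$truth$unstable_gene_ids,
       background = fp$truth$background_gene_ids,
       cq_effects = cq$truth$effects),
  file.path(out, "ground_truth.json"), auto_unbox = FALSE, digits = NA)

cat(sprintf("FPKM panel: %d genes x %d samples in %d datasets\n",
            length(fp$panel$genes), nrow(fp$panel$samples),
            length(unique(fp$panel$samples$dataset_id))))
cat(sprintf("Cq experiment: %d records (%d genes x %d samples x %d tech reps)\n",
            nrow(cq$table$records), length(unique(cq$table$records$gene)),
            length(unique(cq$table$records$sample_id)), design$n_tech_reps))
cat(sprintf("planted stable genes: %s\n",
            paste(fp$truth$stable_gene_ids, collapse = ", ")))
cat("wrote", out, "\n")
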
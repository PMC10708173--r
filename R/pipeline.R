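# End-to-end orchestration: simulate -> screen -> stability -> quantify,
# with a machine-readable run manifest.

#' Pipeline run configuration
#'
#' Validated bundle of everything [run_pipeline()] needs.  All
#' randomness flows from `design$seed`; method names are checked here so
#' a bad configuration fails before any computation.
#'
#' @param out_dir output directory (created if absent).
#' @param design a [simulation_design()]; its `seed` drives the run.
#' @param criteria a [screen_criteria()].
#' @param methods stability methods to run.
#' @param normalization named list of reference-gene sets to compare, or
#'   `NULL` to derive them from the stability ranking (top-3 singletons,
#'   top-3 combined, bottom-2 singletons — the validation contrast).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            design = simulation_design(),
                            criteria = screen_criteria(),
                            methods = c("genorm", "normfinder",
                                        "bestkeeper", "deltact"),
                            normalization = NULL) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(criteria, "screen_criteria"))
  known <- c("genorm", "normfinder", "bestkeeper", "deltact")
  bad <- setdiff(methods, known)
  if (length(bad) > 0L) {
    stop(msg("unknown stability method(s): ", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (length(methods) < 2L) stop("need at least 2 stability methods", call. = FALSE)
  structure(list(out_dir = out_dir, design = design, criteria = criteria,
                 methods = methods, normalization = normalization),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the four stages in order — synthetic-data generation,
#' RNA-seq screening, per-tissue stability ranking, and relative
#' quantification under contrasting normalization schemes — writing every
#' report plus `manifest.json` (seed, per-stage row counts, output files
#' with md5 checksums).  Idempotent: identical configs give
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(config$out_dir, ...)
  stages <- list()
  fail <- function(stage, e) {
    stop(msg("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
         call. = FALSE)
  }

  # -- stage 1: simulate ---------------------------------------------------
  sim <- tryCatch({
    fp <- simulate_fpkm_panel(config$design)
    cq <- simulate_cq_experiment(config$design)
    write_expression_panel(fp$panel, path("expression.tsv"),
                           path("samples.csv"))
    write_cq_table(cq$table, path("cq.csv"))
    jsonlite::write_json(
      list(fpkm_truth = fp$truth[c("stable_gene_ids", "unstable_gene_ids",
                                   "background_gene_ids")],
           cq_truth = cq$truth[c("stable_gene_ids", "unstable_gene_ids")],
           cq_effects = cq$truth$effects),
      path("ground_truth.json"), auto_unbox = FALSE, digits = NA)
    list(fp = fp, cq = cq)
  }, error = function(e) fail("simulate", e))
  stages$simulate <- list(
    fpkm_genes = length(sim$fp$panel$genes),
    fpkm_samples = nrow(sim$fp$panel$samples),
    cq_records = nrow(sim$cq$table$records))

  # -- stage 2: screen -----------------------------------------------------
  screen <- tryCatch({
    rep <- screen_candidates(sim$fp$panel, config$criteria)
    write_screen_report(rep, path("screen_report.tsv"))
    rep
  }, error = function(e) fail("screen", e))
  stages$screen <- list(genes = nrow(screen$per_gene),
                        kept = sum(screen$per_gene$kept),
                        selected = length(screen$selected))

  # -- stage 3: stability --------------------------------------------------
  tissues <- config$design$tissues
  stab <- tryCatch({
    out <- list()
    for (tis in tissues) {
      rep <- rank_stability(sim$cq$table, tissue = tis,
                            methods = config$methods)
      write_stability_report(rep, path(sprintf("stability_%s.tsv", tis)))
      out[[tis]] <- rep
    }
    out
  }, error = function(e) fail("stability", e))
  stages$stability <- list(tissues = tissues,
                           genes = nrow(stab[[1L]]))

  # -- stage 4: quantify ---------------------------------------------------
  quant <- tryCatch({
    target <- sim$cq$truth$unstable_gene_ids[1L]
    fc_all <- list()
    div_all <- list()
    for (tis in tissues) {
      ranking <- stab[[tis]]$gene
      ranking <- setdiff(ranking, target)
      schemes <- config$normalization
      if (is.null(schemes)) {
        top3 <- ranking[1:3]
        bottom2 <- utils::tail(ranking, 2L)
        schemes <- c(stats::setNames(as.list(c(list(top3), top3)),
                                     c(paste(top3, collapse = "+"), top3)),
                     stats::setNames(as.list(bottom2), bottom2))
      }
      cmp <- compare_normalizations(sim$cq$table, target, schemes, tis,
                                    control = config$design$treatments[1L])
      fc_all[[tis]] <- cmp$fold_changes
      if (nrow(cmp$divergence) > 0L) {
        cmp$divergence$tissue <- tis
        div_all[[tis]] <- cmp$divergence
      }
    }
    fc <- do.call(rbind, fc_all)
    write_fold_change(fc, path("fold_change.tsv"))
    div <- do.call(rbind, div_all)
    utils::write.table(div, path("divergence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(fc = fc, div = div)
  }, error = function(e) fail("quantify", e))
  stages$quantify <- list(fold_change_rows = nrow(quant$fc),
                          schemes_compared = nrow(quant$div))

  files <- c("expression.tsv", "samples.csv", "cq.csv", "ground_truth.json",
             "screen_report.tsv",
             sprintf("stability_%s.tsv", tissues),
             "fold_change.tsv", "divergence.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("refstab")),
    seed = config$design$seed,
    stages = stages,
    files = lapply(stats::setNames(files, files), function(f) {
      list(path = f, md5 = unname(tools::md5sum(path(f))))
    }))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
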
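# Synthetic-data generators with planted ground truth.  They emulate the
# study conditions: six RNA-seq datasets spanning varieties, tissues and
# treatments, and a 2-variety x 3-tissue x 3-treatment RT-qPCR experiment
# with three biological and three technical replicates.

#' Simulation design
#'
#' Holds every knob of the synthetic experiments.  Defaults are the study
#' conditions: six RNA-seq datasets, two varieties, leaf/shoot/root,
#' mock (CK) / 30 mM NaCl / air-dry drought, three biological and three
#' technical replicates, stable-gene noise of 0.15 cycles (or log2-FPKM
#' units), planted treatment effects of 1.5 cycles (or log2-fold), a
#' shared per-sample loading effect of 0.3 cycles, technical-replicate
#' noise of 0.1 cycles, and base Cq drawn in 24-34 cycles.
#'
#' @param n_datasets number of RNA-seq datasets.
#' @param varieties,tissues,treatments design factor levels; the first
#'   treatment is the mock/control (calibrator) condition.
#' @param n_bio_reps,n_tech_reps biological / technical replicates.
#' @param n_stable_genes,n_unstable_genes planted candidate genes with
#'   zero / non-zero condition effects; their sum must be at least 3.
#' @param n_background_genes non-candidate genes in the FPKM panel (half
#'   of them form a low-expression stratum for the abundance filter to
#'   remove; all carry condition shifts).
#' @param stable_noise_sd replicate noise SD, cycles (Cq) or log2-FPKM.
#' @param treatment_effect planted condition-shift magnitude, cycles (Cq)
#'   or log2-fold (FPKM); must be non-negative.
#' @param sample_loading_sd SD of the shared per-sample loading effect
#'   added to every gene of a Cq sample, cycles.
#' @param tech_rep_sd technical-replicate noise SD, cycles.
#' @param base_cq_range window for per-gene base Cq, cycles.
#' @param dataset_effect_sd SD of the shared per-dataset log2 offset
#'   applied to all genes of an RNA-seq dataset.
#' @param candidate_baseline_mean,candidate_baseline_sd log2-FPKM baseline
#'   distribution of planted candidate genes.
#' @param seed integer seed; every generator is deterministic given it.
#' @return a list of class `simulation_design`.
#' @export
simulation_design <- function(n_datasets = 6,
                              varieties = c("NPB", "9522"),
                              tissues = c("leaf", "shoot", "root"),
                              treatments = c("CK", "salt", "drought"),
                              n_bio_reps = 3,
                              n_tech_reps = 3,
                              n_stable_genes = 3,
                              n_unstable_genes = 9,
                              n_background_genes = 48,
                              stable_noise_sd = 0.15,
                              treatment_effect = 1.5,
                              sample_loading_sd = 0.3,
                              tech_rep_sd = 0.1,
                              base_cq_range = c(24, 34),
                              dataset_effect_sd = 1.0,
                              candidate_baseline_mean = 6,
                              candidate_baseline_sd = 0.75,
                              seed = 1) {
  d <- list(n_datasets = as.integer(n_datasets),
            varieties = as.character(varieties),
            tissues = as.character(tissues),
            treatments = as.character(treatments),
            n_bio_reps = as.integer(n_bio_reps),
            n_tech_reps = as.integer(n_tech_reps),
            n_stable_genes = as.integer(n_stable_genes),
            n_unstable_genes = as.integer(n_unstable_genes),
            n_background_genes = as.integer(n_background_genes),
            stable_noise_sd = stable_noise_sd,
            treatment_effect = treatment_effect,
            sample_loading_sd = sample_loading_sd,
            tech_rep_sd = tech_rep_sd,
            base_cq_range = base_cq_range,
            dataset_effect_sd = dataset_effect_sd,
            candidate_baseline_mean = candidate_baseline_mean,
            candidate_baseline_sd = candidate_baseline_sd,
            seed = as.integer(seed))
  if (d$n_stable_genes + d$n_unstable_genes < 3L) {
    stop("need at least 3 candidate genes (stable + unstable)", call. = FALSE)
  }
  if (d$stable_noise_sd < 0) stop("stable_noise_sd must be >= 0", call. = FALSE)
  if (d$treatment_effect < 0) stop("treatment_effect must be >= 0", call. = FALSE)
  n_groups <- length(d$varieties) * length(d$treatments)
  if (n_groups < 2L || d$n_bio_reps < 2L) {
    stop("degenerate design: need >=2 condition groups and >=2 biological replicates",
         call. = FALSE)
  }
  structure(d, class = "simulation_design")
}

gene_ids <- function(prefix, n) {
  if (n == 0L) character(0) else sprintf("%s%02d", prefix, seq_len(n))
}

#' Simulate a multi-dataset FPKM panel with planted ground truth
#'
#' Each gene receives one global baseline on the log2-FPKM scale; every
#' dataset adds a shared log2 offset to all genes (global expression-level
#' differences between sequencing experiments — the component that makes
#' co-stable housekeeping genes correlate across datasets).  Stable genes
#' then vary only by replicate noise; unstable candidate genes and all
#' background genes additionally receive a per-dataset condition-group
#' shift of magnitude `treatment_effect` log2-fold with randomized sign.
#' Candidate baselines are drawn from a normal truncated below at
#' `candidate_baseline_mean - 1` — a candidate reference gene is by
#' definition abundantly expressed.  Half of the background genes form a
#' low-expression stratum (baseline log2-FPKM around -1) so the abundance
#' filter has something to remove.
#' FPKM is `2^log2value`, hence non-negative.  Deterministic given
#' `design$seed`.
#'
#' @param design a [simulation_design()].
#' @return list with `panel` (an [expression_panel()]) and `truth`, a list
#'   with `stable_gene_ids`, `unstable_gene_ids`, `background_gene_ids`,
#'   a per-gene `effect_size` map (0 for stable genes) and an `effects`
#'   data.frame of every planted (dataset, gene, group) shift.
#' @export
simulate_fpkm_panel <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  with_seed(d$seed, {
    stable <- gene_ids("STB", d$n_stable_genes)
    unstable <- gene_ids("UNS", d$n_unstable_genes)
    n_low <- d$n_background_genes %/% 2L
    bg_high <- gene_ids("BGH", d$n_background_genes - n_low)
    bg_low <- gene_ids("BGL", n_low)
    genes <- c(stable, unstable, bg_high, bg_low)

    # Candidate baselines come from a normal truncated at mean - 1:
    # candidates are by definition abundantly expressed, so they must
    # clear the abundance criterion in every dataset.
    n_cand <- length(stable) + length(unstable)
    lo <- stats::pnorm(d$candidate_baseline_mean - 1,
                       d$candidate_baseline_mean, d$candidate_baseline_sd)
    baseline <- c(
      stats::qnorm(stats::runif(n_cand, lo, 1),
                   d$candidate_baseline_mean, d$candidate_baseline_sd),
      stats::rnorm(length(bg_high), 4, 1.5),
      stats::rnorm(length(bg_low), -1, 1)
    )
    names(baseline) <- genes
    shifted_genes <- c(unstable, bg_high, bg_low)

    meta_list <- list()
    fpkm_cols <- list()
    effects <- list()
    for (k in seq_len(d$n_datasets)) {
      ds_id <- sprintf("DS%02d", k)
      tissue <- d$tissues[(k - 1L) %% length(d$tissues) + 1L]
      grid <- expand.grid(bio_rep = seq_len(d$n_bio_reps),
                          treatment = d$treatments,
                          variety = d$varieties,
                          stringsAsFactors = FALSE)
      grid$tissue <- tissue
      grid$dataset_id <- ds_id
      grid$sample_id <- sprintf("%s_%s_%s_%s_r%d", ds_id, grid$variety,
                                tissue, grid$treatment, grid$bio_rep)
      group <- paste(grid$variety, grid$treatment, sep = ".")
      groups <- unique(group)

      ds_offset <- stats::rnorm(1, 0, d$dataset_effect_sd)
      shift <- matrix(0, nrow = length(genes), ncol = length(groups),
                      dimnames = list(genes, groups))
      if (d$treatment_effect > 0 && length(shifted_genes) > 0L) {
        # magnitude up to treatment_effect, sign randomized per gene x group
        n_sh <- length(shifted_genes) * length(groups)
        signs <- matrix(sample(c(-1, 1), n_sh, replace = TRUE),
                        nrow = length(shifted_genes))
        mags <- matrix(stats::runif(n_sh, 0, d$treatment_effect),
                       nrow = length(shifted_genes))
        shift[shifted_genes, ] <- signs * mags
      }
      log2val <- baseline + ds_offset +
        shift[, match(group, groups), drop = FALSE] +
        matrix(stats::rnorm(length(genes) * nrow(grid), 0, d$stable_noise_sd),
               nrow = length(genes))
      fpkm_cols[[k]] <- 2^log2val
      meta_list[[k]] <- grid
      effects[[k]] <- data.frame(dataset_id = ds_id,
                                 gene = rep(genes, times = length(groups)),
                                 group = rep(groups, each = length(genes)),
                                 shift_log2 = as.vector(shift),
                                 stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, meta_list)[, SAMPLE_META_COLS]
    fpkm <- do.call(cbind, fpkm_cols)
    colnames(fpkm) <- meta$sample_id
    rownames(fpkm) <- genes

    effect_size <- stats::setNames(
      ifelse(genes %in% stable, 0, d$treatment_effect), genes)
    truth <- list(stable_gene_ids = stable,
                  unstable_gene_ids = unstable,
                  background_gene_ids = c(bg_high, bg_low),
                  effect_size = effect_size,
                  effects = do.call(rbind, effects))
    list(panel = expression_panel(fpkm, meta), truth = truth)
  })
}

#' Simulate an RT-qPCR Cq experiment with planted ground truth
#'
#' Per gene, a base Cq is drawn uniformly inside `base_cq_range`.  Stable
#' genes vary only by biological noise; unstable genes additionally get a
#' tissue-by-treatment shift of magnitude `treatment_effect` cycles
#' (jittered by +/-10% per gene and cell so no two genes share an
#' identical response pattern) with randomized sign, and zero under the
#' control treatment so the calibrator stays clean.  A shared per-sample loading effect
#' (`Normal(0, sample_loading_sd)`) is added to every gene of a sample —
#' the structure that sample-centering and ratio-based stability methods
#' cancel but raw-Cq descriptive statistics do not.  Technical replicates
#' add `Normal(0, tech_rep_sd)` cycles.  Deterministic given
#' `design$seed`.
#'
#' @param design a [simulation_design()].
#' @return list with `table` (a [cq_table()], technical replicates not
#'   aggregated) and `truth`: `stable_gene_ids`, `unstable_gene_ids`,
#'   per-gene `effect_size`, and `effects`, a data.frame of planted
#'   (gene, tissue, treatment) shifts in cycles.
#' @export
simulate_cq_experiment <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  with_seed(d$seed, {
    stable <- gene_ids("STB", d$n_stable_genes)
    unstable <- gene_ids("UNS", d$n_unstable_genes)
    genes <- c(stable, unstable)

    base_cq <- stats::runif(length(genes), d$base_cq_range[1L],
                            d$base_cq_range[2L])
    names(base_cq) <- genes

    samples <- expand.grid(bio_rep = seq_len(d$n_bio_reps),
                           treatment = d$treatments,
                           tissue = d$tissues,
                           variety = d$varieties,
                           stringsAsFactors = FALSE)
    samples$sample_id <- sprintf("%s_%s_%s_r%d", samples$variety,
                                 samples$tissue, samples$treatment,
                                 samples$bio_rep)
    loading <- stats::rnorm(nrow(samples), 0, d$sample_loading_sd)

    # Planted shifts: gene x (tissue, treatment); control treatment = 0.
    # Magnitudes are treatment_effect up to a +/-10% per gene x cell
    # jitter, so no two genes share the exact same response pattern, as
    # no two real genes would.
    cells <- expand.grid(treatment = d$treatments, tissue = d$tissues,
                         stringsAsFactors = FALSE)
    effects <- do.call(rbind, lapply(genes, function(g) {
      sh <- ifelse(cells$treatment == d$treatments[1L] | g %in% stable,
                   0,
                   sample(c(-1, 1), nrow(cells), replace = TRUE) *
                     stats::runif(nrow(cells), 0.9, 1.1) *
                     d$treatment_effect)
      data.frame(gene = g, tissue = cells$tissue,
                 treatment = cells$treatment, shift_cycles = sh,
                 stringsAsFactors = FALSE)
    }))

    shift_for <- function(g, tis, trt) {
      effects$shift_cycles[effects$gene == g & effects$tissue == tis &
                             effects$treatment == trt]
    }
    recs <- list()
    i <- 0L
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      for (si in seq_len(nrow(samples))) {
        mu <- base_cq[g] + loading[si] +
          shift_for(g, samples$tissue[si], samples$treatment[si]) +
          stats::rnorm(1, 0, d$stable_noise_sd)
        tr <- mu + stats::rnorm(d$n_tech_reps, 0, d$tech_rep_sd)
        i <- i + 1L
        recs[[i]] <- data.frame(gene = g,
                                sample_id = samples$sample_id[si],
                                variety = samples$variety[si],
                                tissue = samples$tissue[si],
                                treatment = samples$treatment[si],
                                bio_rep = samples$bio_rep[si],
                                tech_rep = seq_len(d$n_tech_reps),
                                cq = tr,
                                stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, recs)
    effect_size <- stats::setNames(
      ifelse(genes %in% stable, 0, d$treatment_effect), genes)
    truth <- list(stable_gene_ids = stable, unstable_gene_ids = unstable,
                  effect_size = effect_size, effects = effects)
    list(table = cq_table(records), truth = truth)
  })
}

#' Simulate a serial-dilution Cq series
#'
#' Generates `Cq(d) = intercept - log10(dilution_d) / log10(E) + noise`
#' over `n_points` dilutions spaced `step_log10` apart, the inverse model
#' of [fit_standard_curve()]: a noiseless series at efficiency E is
#' recovered exactly.
#'
#' @param efficiency amplification efficiency E, fold per cycle, in
#'   (1, 3); E = 2 is 100%.
#' @param n_points number of dilution points (>= 3).
#' @param step_log10 log10 spacing between successive dilutions.
#' @param noise_sd Cq noise SD, cycles.
#' @param seed integer seed.
#' @param intercept Cq at dilution 1, cycles.
#' @param gene label for the `gene` column.
#' @return data.frame with columns `gene`, `log10_dilution`, `cq`.
#' @export
simulate_dilution_series <- function(efficiency, n_points = 6,
                                     step_log10 = 1, noise_sd = 0,
                                     seed = 1, intercept = 24,
                                     gene = "target") {
  if (!is.numeric(efficiency) || efficiency <= 1 || efficiency >= 3) {
    stop("efficiency must lie in (1, 3) fold per cycle", call. = FALSE)
  }
  if (n_points < 3) stop("need at least 3 dilution points", call. = FALSE)
  with_seed(seed, {
    lg <- -(seq_len(n_points) - 1) * step_log10
    cq <- intercept - lg / log10(efficiency) +
      stats::rnorm(n_points, 0, noise_sd)
    data.frame(gene = gene, log10_dilution = lg, cq = cq,
               stringsAsFactors = FALSE)
  })
}
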
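# Standard-curve efficiency estimation and relative-expression
# quantification of target genes against single or combined reference
# genes.

#' Fit a standard curve and estimate amplification efficiency
#'
#' Least-squares line of Cq versus log10(dilution).  The efficiency in
#' percent is `100 * (10^(-1/slope) - 1)`: a slope of -3.3219 cycles per
#' 10-fold dilution is 100% (E = 2).
#'
#' @param series data.frame with columns `log10_dilution` and `cq`
#'   (e.g. from [read_dilution_series()] or
#'   [simulate_dilution_series()]); at least 3 points spanning at least
#'   2 log10 units.
#' @return list of class `efficiency_fit`: `slope`, `intercept`,
#'   `r_squared`, `efficiency_pct`, `efficiency` (fold per cycle),
#'   `n_points`.
#' @export
fit_standard_curve <- function(series) {
  need <- c("log10_dilution", "cq")
  if (!all(need %in% names(series))) {
    stop("series needs columns log10_dilution and cq", call. = FALSE)
  }
  if (nrow(series) < 3L) stop("need at least 3 dilution points", call. = FALSE)
  span <- diff(range(series$log10_dilution))
  if (span < 2) {
    stop("dilution series must span at least 2 log10 units", call. = FALSE)
  }
  fit <- stats::lm(cq ~ log10_dilution, data = series)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) {
    stop("positive slope: inverted dilution axis?", call. = FALSE)
  }
  # R^2 computed directly (summary.lm warns on noiseless series)
  ss_tot <- sum((series$cq - mean(series$cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  eff <- 10^(-1 / slope)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 efficiency = eff,
                 efficiency_pct = 100 * (eff - 1),
                 n_points = nrow(series)),
            class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("standard curve: slope %.4f, R^2 %.4f, efficiency %.2f%%\n",
              x$slope, x$r_squared, x$efficiency_pct))
  invisible(x)
}

gene_efficiency <- function(table, genes, efficiency,
                            use_efficiencies) {
  eff <- rep(efficiency, length(genes))
  names(eff) <- genes
  if (use_efficiencies && !is.null(table$efficiencies)) {
    hit <- intersect(genes, names(table$efficiencies))
    eff[hit] <- table$efficiencies[hit]
  }
  eff
}

#' Per-sample normalization factor
#'
#' `NF_s` is the geometric mean over the reference set of
#' `E_r^(-Cq_rs)`, defined up to a per-gene constant that cancels in
#' ratios; a singleton set reduces to the classic single-reference
#' scheme.
#'
#' @param table a [cq_table()] (technical replicates aggregated).
#' @param refs character vector of reference gene ids (non-empty).
#' @param sample sample id.
#' @param efficiency default efficiency for genes without a per-gene fit.
#' @param use_efficiencies use `table$efficiencies` when present.
#' @return positive scalar.
#' @export
normalization_factor <- function(table, refs, sample, efficiency = 2,
                                 use_efficiencies = FALSE) {
  stopifnot(inherits(table, "cq_table"))
  if (length(refs) == 0L) stop("reference set is empty", call. = FALSE)
  r <- table$records
  eff <- gene_efficiency(table, unique(refs), efficiency, use_efficiencies)
  qs <- vapply(refs, function(g) {
    cq <- r$cq[r$gene == g & r$sample_id == sample]
    if (length(cq) == 0L) {
      stop(msg("no Cq for reference '", g, "' in sample '", sample, "'"),
           call. = FALSE)
    }
    eff[g]^(-mean(cq))
  }, numeric(1))
  geo_mean(qs)
}

#' Relative expression of a target gene
#'
#' Efficiency-corrected ratio per biological replicate:
#' `E_t^(Cq_t,cal - Cq_t,s) / prod_r E_r^(Cq_r,cal - Cq_r,s)^(1/|refs|)`,
#' where the calibrator Cq of every gene is its arithmetic mean Cq over
#' the tissue's control (first-treatment / CK) replicates.  With all
#' efficiencies 2 this is the classic `2^(-ddCq)`; per-gene fitted
#' efficiencies are used only when `use_efficiencies = TRUE` (plain
#' `2^(-ddCq)` is the default).
#'
#' @param table a [cq_table()]; technical replicates are aggregated
#'   automatically.
#' @param target target gene id.
#' @param refs character vector of reference gene ids.
#' @param tissue tissue to quantify in.
#' @param control treatment level serving as calibrator (default
#'   `"CK"`).
#' @param efficiency default efficiency.
#' @param use_efficiencies use per-gene efficiencies from the table.
#' @param scheme label stored in the output (defaults to the ref set).
#' @return data.frame of class `fold_change_table`: one row per sample
#'   with `target`, `tissue`, `treatment`, `variety`, `bio_rep`,
#'   `sample_id`, `scheme`, `log2_fc`, `fold_change`.
#' @export
relative_expression <- function(table, target, refs, tissue,
                                control = "CK", efficiency = 2,
                                use_efficiencies = FALSE,
                                scheme = paste(refs, collapse = "+")) {
  stopifnot(inherits(table, "cq_table"))
  if (length(refs) == 0L) stop("reference set is empty", call. = FALSE)
  if (anyDuplicated(table$records[, c("gene", "sample_id")])) {
    table <- aggregate_tech_reps(table)
  }
  genes <- unique(c(target, refs))
  r <- table$records
  r <- r[r$tissue == tissue & r$gene %in% genes, , drop = FALSE]
  if (nrow(r) == 0L) stop(msg("no records for tissue '", tissue, "'"), call. = FALSE)
  missing_genes <- setdiff(genes, unique(r$gene))
  if (length(missing_genes) > 0L) {
    stop(msg("gene(s) not measured in tissue '", tissue, "': ",
             paste(missing_genes, collapse = ", ")), call. = FALSE)
  }
  if (!any(r$treatment == control)) {
    stop(msg("no '", control, "' samples in tissue '", tissue, "'"),
         call. = FALSE)
  }
  eff <- gene_efficiency(table, genes, efficiency, use_efficiencies)

  cal <- vapply(genes, function(g) {
    mean(r$cq[r$gene == g & r$treatment == control])
  }, numeric(1))

  samp <- unique(r[, c("sample_id", "variety", "treatment", "bio_rep")])
  log2_fc <- vapply(seq_len(nrow(samp)), function(i) {
    s <- samp$sample_id[i]
    cq_of <- function(g) {
      v <- r$cq[r$gene == g & r$sample_id == s]
      if (length(v) != 1L) {
        stop(msg("expected one Cq for gene '", g, "' in sample '", s, "'"),
             call. = FALSE)
      }
      v
    }
    t_term <- (cal[target] - cq_of(target)) * log2(eff[target])
    r_term <- mean(vapply(refs, function(g) {
      (cal[g] - cq_of(g)) * log2(eff[g])
    }, numeric(1)))
    t_term - r_term
  }, numeric(1))

  out <- data.frame(target = target, tissue = tissue,
                    treatment = samp$treatment, variety = samp$variety,
                    bio_rep = samp$bio_rep, sample_id = samp$sample_id,
                    scheme = scheme, log2_fc = log2_fc,
                    fold_change = 2^log2_fc, stringsAsFactors = FALSE)
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Summarize fold changes per condition
#'
#' Biological-replicate statistics are computed on log2 fold changes
#' (symmetric errors) and reported back on the linear scale: `mean_fc`
#' is the geometric mean, so the control condition's mean is exactly 1.
#'
#' @param fc a [relative_expression()] result.
#' @return data.frame with `target`, `tissue`, `scheme`, `treatment`,
#'   `mean_fc`, `sd_log2`, `n`.
#' @export
summarize_fold_changes <- function(fc) {
  agg <- stats::aggregate(fc["log2_fc"],
                          by = fc[c("target", "tissue", "scheme", "treatment")],
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- agg[, 1:4]
  out$mean_fc <- 2^agg$log2_fc[, "mean"]
  out$sd_log2 <- agg$log2_fc[, "sd"]
  out$n <- as.integer(agg$log2_fc[, "n"])
  out[order(out$target, out$tissue, out$scheme, out$treatment), ]
}

#' Compare normalization schemes
#'
#' Computes the target's fold-change profile under each scheme (a named
#' list of reference sets) and summarizes how far each scheme's
#' per-condition geometric-mean profile deviates from the first
#' (reference) scheme: the maximum over conditions of
#' `|log2 FC_scheme - log2 FC_reference|`.
#'
#' @inheritParams relative_expression
#' @param schemes named list of character vectors of reference genes
#'   (at least 1; the first is the reference scheme).
#' @return list with `fold_changes` (row-bound per-sample tables) and
#'   `divergence` (data.frame `scheme`, `max_abs_log2_diff`; empty with
#'   a single scheme).
#' @export
compare_normalizations <- function(table, target, schemes, tissue,
                                   control = "CK", efficiency = 2,
                                   use_efficiencies = FALSE) {
  if (length(schemes) < 1L) stop("need at least 1 scheme", call. = FALSE)
  if (is.null(names(schemes))) {
    names(schemes) <- vapply(schemes, paste, character(1), collapse = "+")
  }
  fcs <- lapply(names(schemes), function(nm) {
    relative_expression(table, target, schemes[[nm]], tissue,
                        control = control, efficiency = efficiency,
                        use_efficiencies = use_efficiencies, scheme = nm)
  })
  names(fcs) <- names(schemes)
  all_fc <- do.call(rbind, fcs)

  profile_of <- function(fc) {
    s <- stats::aggregate(fc["log2_fc"], by = fc["treatment"], FUN = mean)
    stats::setNames(s$log2_fc, s$treatment)
  }
  if (length(schemes) > 1L) {
    ref_prof <- profile_of(fcs[[1L]])
    div <- vapply(names(schemes)[-1L], function(nm) {
      p <- profile_of(fcs[[nm]])
      max(abs(p[names(ref_prof)] - ref_prof))
    }, numeric(1))
    divergence <- data.frame(scheme = names(div),
                             reference_scheme = names(schemes)[1L],
                             max_abs_log2_diff = unname(div),
                             stringsAsFactors = FALSE)
  } else {
    divergence <- data.frame(scheme = character(0),
                             reference_scheme = character(0),
                             max_abs_log2_diff = numeric(0),
                             stringsAsFactors = FALSE)
  }
  list(fold_changes = all_fc, divergence = divergence)
}
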
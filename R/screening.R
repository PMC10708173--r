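# Candidate-selection cascade on an ExpressionPanel: abundance filter,
# ratio-window filter, one-way ANOVA stability filter, cross-dataset
# presence count, and correlation-based final ranking.

#' Screening criteria
#'
#' Thresholds of the five-stage candidate-selection cascade.  Defaults
#' are the published cascade: mean expression above 70% of the dataset's
#' grand-mean FPKM, per-group ratio to the gene's dataset mean inside
#' 0.75-1.25, ANOVA p > 0.05 (the filter *retains* non-significant
#' genes), presence in at least two datasets, and a positive pairwise
#' Pearson r-squared of at least 0.95 at p < 0.01.
#'
#' @param abundance_fraction fraction of the dataset grand-mean FPKM a
#'   gene's mean must exceed.
#' @param ratio_low,ratio_high admissible window for (group mean)/(gene
#'   dataset mean); requires `0 < ratio_low < 1 < ratio_high`.
#' @param anova_alpha one-way ANOVA significance level; genes with
#'   p > `anova_alpha` pass.
#' @param min_dataset_presence minimum number of datasets in which a gene
#'   must pass all three filters.
#' @param corr_r2_threshold minimum correlation score (aggregated
#'   positive r-squared against the other kept genes).
#' @param corr_alpha significance level the best-partner correlation must
#'   beat.
#' @param corr_aggregate how per-partner r-squared values are combined
#'   into one score: `"median"` (default), `"mean"` or `"max"`.
#' @return a list of class `screen_criteria`.
#' @export
screen_criteria <- function(abundance_fraction = 0.70,
                            ratio_low = 0.75, ratio_high = 1.25,
                            anova_alpha = 0.05,
                            min_dataset_presence = 2L,
                            corr_r2_threshold = 0.95,
                            corr_alpha = 0.01,
                            corr_aggregate = c("median", "mean", "max")) {
  corr_aggregate <- match.arg(corr_aggregate)
  if (!(ratio_low > 0 && ratio_low < 1 && ratio_high > 1)) {
    stop("need 0 < ratio_low < 1 < ratio_high", call. = FALSE)
  }
  if (anova_alpha < 0 || anova_alpha > 1 || corr_alpha < 0 || corr_alpha > 1) {
    stop("alpha levels must lie in [0, 1]", call. = FALSE)
  }
  structure(list(abundance_fraction = abundance_fraction,
                 ratio_low = ratio_low, ratio_high = ratio_high,
                 anova_alpha = anova_alpha,
                 min_dataset_presence = as.integer(min_dataset_presence),
                 corr_r2_threshold = corr_r2_threshold,
                 corr_alpha = corr_alpha,
                 corr_aggregate = corr_aggregate),
            class = "screen_criteria")
}

dataset_ids <- function(panel) unique(panel$samples$dataset_id)

#' Abundance filter
#'
#' Within each dataset, a gene passes when its mean FPKM exceeds
#' `abundance_fraction` times the grand mean FPKM over all genes and
#' samples of that dataset.
#'
#' @param panel an [expression_panel()].
#' @param criteria a [screen_criteria()].
#' @return logical genes x datasets matrix.
#' @export
abundance_filter <- function(panel, criteria = screen_criteria()) {
  stopifnot(inherits(panel, "expression_panel"))
  ds <- dataset_ids(panel)
  out <- matrix(NA, nrow = length(panel$genes), ncol = length(ds),
                dimnames = list(panel$genes, ds))
  for (d in ds) {
    sub <- panel$fpkm[, panel$samples$dataset_id == d, drop = FALSE]
    grand <- mean(sub)
    if (grand == 0) {
      stop(msg("dataset '", d, "' has an all-zero FPKM matrix"), call. = FALSE)
    }
    out[, d] <- rowMeans(sub) > criteria$abundance_fraction * grand
  }
  out
}

#' Ratio-window filter
#'
#' For each dataset, every condition group's mean FPKM of the gene,
#' divided by the gene's dataset-wide mean, must lie inside
#' `[ratio_low, ratio_high]`.  A gene with zero dataset-wide mean fails
#' as "not expressed" rather than raising a division error.
#'
#' @inheritParams abundance_filter
#' @return logical genes x datasets matrix.
#' @export
ratio_window_filter <- function(panel, criteria = screen_criteria()) {
  stopifnot(inherits(panel, "expression_panel"))
  ds <- dataset_ids(panel)
  out <- matrix(NA, nrow = length(panel$genes), ncol = length(ds),
                dimnames = list(panel$genes, ds))
  for (d in ds) {
    idx <- panel$samples$dataset_id == d
    sub <- panel$fpkm[, idx, drop = FALSE]
    grp <- condition_groups(panel$samples[idx, , drop = FALSE])
    gene_mean <- rowMeans(sub)
    group_means <- vapply(levels(grp), function(g) {
      rowMeans(sub[, grp == g, drop = FALSE])
    }, numeric(nrow(sub)))
    if (is.null(dim(group_means))) {
      group_means <- matrix(group_means, nrow = nrow(sub))
    }
    ratio <- group_means / gene_mean          # rows recycle gene_mean
    pass <- apply(ratio >= criteria$ratio_low & ratio <= criteria$ratio_high,
                  1L, all)
    pass[gene_mean == 0] <- FALSE             # not expressed
    out[, d] <- pass
  }
  out
}

# One-way ANOVA p-value with the degenerate conventions: zero
# within-group variance everywhere and equal means -> p = 1; differing
# means with zero variance -> p = 0.  Non-degenerate cases use the
# standard F test via lm/anova.
oneway_anova_p <- function(y, grp) {
  grp <- droplevels(as.factor(grp))
  if (nlevels(grp) < 2L) return(NA_real_)
  means <- tapply(y, grp, mean)
  ssw <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2)))
  if (ssw == 0) {
    return(if (max(means) - min(means) == 0) 1 else 0)
  }
  fit <- stats::anova(stats::lm(y ~ grp))
  fit[["Pr(>F)"]][1L]
}

#' ANOVA stability filter
#'
#' One-way ANOVA of each gene's FPKM across the dataset's condition
#' groups (the cross of the varying design factors); a gene passes when
#' p > `anova_alpha` — i.e., the filter keeps genes whose expression does
#' *not* change significantly.  Datasets flagged at panel construction as
#' unable to support ANOVA yield `NA`.
#'
#' @inheritParams abundance_filter
#' @return list with numeric matrix `p` and logical matrix `pass`, both
#'   genes x datasets.
#' @export
anova_filter <- function(panel, criteria = screen_criteria()) {
  stopifnot(inherits(panel, "expression_panel"))
  ds <- dataset_ids(panel)
  excluded <- attr(panel, "anova_excluded")
  p <- matrix(NA_real_, nrow = length(panel$genes), ncol = length(ds),
              dimnames = list(panel$genes, ds))
  for (d in setdiff(ds, excluded)) {
    idx <- panel$samples$dataset_id == d
    sub <- panel$fpkm[, idx, drop = FALSE]
    grp <- condition_groups(panel$samples[idx, , drop = FALSE])
    p[, d] <- apply(sub, 1L, oneway_anova_p, grp = grp)
  }
  list(p = p, pass = p > criteria$anova_alpha)
}

#' Cross-dataset presence count
#'
#' Number of datasets in which a gene passes the abundance, ratio-window
#' and ANOVA filters simultaneously; genes reaching
#' `min_dataset_presence` are kept for the correlation stage.  Datasets
#' where the ANOVA could not be computed contribute nothing.
#'
#' @param abundance,ratio logical genes x datasets matrices from
#'   [abundance_filter()] / [ratio_window_filter()].
#' @param anova_pass logical matrix from [anova_filter()]`$pass`.
#' @param criteria a [screen_criteria()].
#' @return data.frame with columns `gene`, `presence_count`, `kept`.
#' @export
presence_count <- function(abundance, ratio, anova_pass,
                           criteria = screen_criteria()) {
  all_pass <- abundance & ratio & anova_pass
  all_pass[is.na(all_pass)] <- FALSE
  data.frame(gene = rownames(abundance),
             presence_count = rowSums(all_pass),
             kept = rowSums(all_pass) >= criteria$min_dataset_presence,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Per-gene mean log2(FPKM + 1) profile over (dataset, tissue, treatment)
# cells; genes in columns.
expression_profiles <- function(panel, genes) {
  cell <- interaction(panel$samples$dataset_id, panel$samples$tissue,
                      panel$samples$treatment, drop = TRUE, lex.order = TRUE)
  lg <- log2(panel$fpkm[genes, , drop = FALSE] + 1)
  prof <- t(apply(lg, 1L, function(v) tapply(v, cell, mean)))
  if (length(genes) == 1L) prof <- matrix(prof, nrow = 1L,
                                          dimnames = list(genes, levels(cell)))
  t(prof)   # cells x genes
}

#' Correlation-based final ranking
#'
#' Each kept gene's expression profile is its mean log2(FPKM + 1) per
#' (dataset, tissue, treatment) cell.  Pairwise Pearson correlations are
#' computed between profiles; a gene's score aggregates the r-squared of
#' its positively correlated partners (negative-r partners contribute 0).
#' A gene is selected when its score reaches `corr_r2_threshold` and its
#' best partner's correlation p-value beats `corr_alpha`.  Genes with a
#' zero-variance profile get score 0 and the reason `"zero_variance"`.
#'
#' @param panel an [expression_panel()].
#' @param kept_genes character vector of genes surviving the presence
#'   stage (at least 3).
#' @param criteria a [screen_criteria()].
#' @return data.frame with columns `gene`, `correlation_score`,
#'   `best_partner`, `best_partner_p`, `selected`, `reason`.
#' @export
correlation_rank <- function(panel, kept_genes,
                             criteria = screen_criteria()) {
  stopifnot(inherits(panel, "expression_panel"))
  if (length(kept_genes) < 3L) {
    stop("correlation ranking needs at least 3 kept genes", call. = FALSE)
  }
  prof <- expression_profiles(panel, kept_genes)
  if (nrow(prof) < 3L) {
    stop("correlation ranking needs at least 3 condition cells", call. = FALSE)
  }
  sds <- apply(prof, 2L, stats::sd)
  out <- data.frame(gene = kept_genes, correlation_score = 0,
                    best_partner = NA_character_, best_partner_p = NA_real_,
                    selected = FALSE, reason = "", stringsAsFactors = FALSE)
  ok <- sds > 0
  if (sum(ok) >= 2L) {
    r <- stats::cor(prof[, ok, drop = FALSE])
    for (g in kept_genes[ok]) {
      partners <- setdiff(kept_genes[ok], g)
      if (length(partners) == 0L) break
      rv <- r[g, partners]
      contrib <- ifelse(rv > 0, rv^2, 0)
      score <- switch(criteria$corr_aggregate,
                      median = stats::median(contrib),
                      mean = mean(contrib),
                      max = max(contrib))
      best <- partners[which.max(rv)]
      pv <- stats::cor.test(prof[, g], prof[, best])$p.value
      i <- match(g, out$gene)
      out$correlation_score[i] <- score
      out$best_partner[i] <- best
      out$best_partner_p[i] <- pv
      out$selected[i] <- score >= criteria$corr_r2_threshold &&
        is.finite(pv) && pv < criteria$corr_alpha
    }
  }
  out$reason[!ok] <- "zero_variance"
  out
}

#' Run the full screening cascade
#'
#' Composes the abundance, ratio-window and ANOVA filters, the
#' cross-dataset presence count and the correlation ranking, recording
#' every intermediate decision.  Deterministic; gene and sample order do
#' not affect any decision.
#'
#' @param panel an [expression_panel()].
#' @param criteria a [screen_criteria()].
#' @return an object of class `screen_report`: list with `per_dataset`
#'   (long data.frame of per-(gene, dataset) filter outcomes), `per_gene`
#'   (presence count, correlation score, `selected` flag), `selected`
#'   (character vector) and `criteria`.
#' @export
screen_candidates <- function(panel, criteria = screen_criteria()) {
  stopifnot(inherits(panel, "expression_panel"))
  if (length(panel$genes) == 0L) {
    return(structure(list(
      per_dataset = data.frame(gene = character(0), dataset_id = character(0),
                               abundance_pass = logical(0), ratio_pass = logical(0),
                               anova_p = numeric(0), anova_pass = logical(0)),
      per_gene = data.frame(gene = character(0), presence_count = integer(0),
                            kept = logical(0), correlation_score = numeric(0),
                            best_partner = character(0), best_partner_p = numeric(0),
                            selected = logical(0), reason = character(0)),
      selected = character(0), criteria = criteria), class = "screen_report"))
  }
  ab <- abundance_filter(panel, criteria)
  ra <- ratio_window_filter(panel, criteria)
  an <- anova_filter(panel, criteria)
  pres <- presence_count(ab, ra, an$pass, criteria)

  ds <- colnames(ab)
  per_dataset <- data.frame(
    gene = rep(rownames(ab), times = length(ds)),
    dataset_id = rep(ds, each = nrow(ab)),
    abundance_pass = as.vector(ab),
    ratio_pass = as.vector(ra),
    anova_p = as.vector(an$p),
    anova_pass = as.vector(an$pass),
    stringsAsFactors = FALSE)

  kept <- pres$gene[pres$kept]
  if (length(kept) >= 3L) {
    corr <- correlation_rank(panel, kept, criteria)
  } else {
    corr <- data.frame(gene = kept, correlation_score = NA_real_,
                       best_partner = NA_character_, best_partner_p = NA_real_,
                       selected = FALSE,
                       reason = "fewer than 3 kept genes",
                       stringsAsFactors = FALSE)
  }
  per_gene <- merge(pres, corr, by = "gene", all.x = TRUE, sort = TRUE)
  per_gene$selected[is.na(per_gene$selected)] <- FALSE
  per_gene <- per_gene[order(per_gene$gene), , drop = FALSE]
  rownames(per_gene) <- NULL

  structure(list(per_dataset = per_dataset, per_gene = per_gene,
                 selected = sort(per_gene$gene[per_gene$selected]),
                 criteria = criteria),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen_report:", nrow(x$per_gene), "genes,",
      sum(x$per_gene$kept), "kept,",
      length(x$selected), "selected\n")
  if (length(x$selected) > 0L) {
    cat("selected:", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a screening report as TSV
#'
#' Writes the per-gene table with a header block (`#`-prefixed) recording
#' the criteria and the correlation aggregation choice.
#'
#' @param report a `screen_report`.
#' @param path output path.
#' @return invisibly, `report`.
#' @export
write_screen_report <- function(report, path) {
  stopifnot(inherits(report, "screen_report"))
  con <- file(path, "w")
  on.exit(close(con))
  cr <- report$criteria
  writeLines(c(
    msg("# screen_report"),
    msg("# abundance_fraction=", cr$abundance_fraction,
        " ratio_window=[", cr$ratio_low, ",", cr$ratio_high, "]",
        " anova_alpha=", cr$anova_alpha,
        " min_dataset_presence=", cr$min_dataset_presence),
    msg("# corr_r2_threshold=", cr$corr_r2_threshold,
        " corr_alpha=", cr$corr_alpha,
        " corr_aggregate=", cr$corr_aggregate)), con)
  utils::write.table(report$per_gene, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}
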
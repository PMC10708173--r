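# The four RT-qPCR stability algorithms (geNorm, NormFinder, BestKeeper,
# comparative delta-Ct) and the geometric-mean comprehensive rank.
# All operate per tissue on a complete genes x samples Cq grid.

#' Convert Cq to relative quantities
#'
#' `Q_gs = E_g^(minCq_g - Cq_gs)`: the classic geNorm pre-transform.
#' With all efficiencies equal to 2 this is `2^(-dCq)` to the per-gene
#' minimum, so the per-gene maximum quantity is 1.
#'
#' @param table a [cq_table()] (technical replicates already aggregated).
#' @param tissue tissue to subset to, or `NULL` for all samples.
#' @param efficiency default amplification efficiency used for genes
#'   without an entry in `table$efficiencies`.
#' @param drop_incomplete_samples drop samples missing any gene instead
#'   of erroring.
#' @return an object of class `quantity_matrix`: list with `q` (genes x
#'   samples, values in (0, 1]), `cq` (the Cq grid), `samples` (metadata),
#'   `groups` (treatment factor), `tissue`, `efficiency` (per-gene
#'   vector).
#' @export
to_quantities <- function(table, tissue = NULL, efficiency = 2,
                          drop_incomplete_samples = FALSE) {
  stopifnot(inherits(table, "cq_table"))
  cm <- cq_matrix(table, tissue = tissue,
                  drop_incomplete_samples = drop_incomplete_samples)
  genes <- rownames(cm$cq)
  eff <- rep(efficiency, length(genes))
  names(eff) <- genes
  if (!is.null(table$efficiencies)) {
    hit <- intersect(genes, names(table$efficiencies))
    eff[hit] <- table$efficiencies[hit]
  }
  q <- eff^(apply(cm$cq, 1L, min) - cm$cq)
  structure(list(q = q, cq = cm$cq, samples = cm$samples,
                 groups = factor(cm$samples$treatment),
                 tissue = tissue, efficiency = eff),
            class = "quantity_matrix")
}

# log-ratio pairwise variation V_jk = SD over samples of log2(Q_j / Q_k),
# and M_j = mean over partners.  Returns the M vector for the given gene
# subset.
genorm_m_values <- function(logq) {
  n <- nrow(logq)
  m <- numeric(n)
  for (j in seq_len(n)) {
    v <- vapply(seq_len(n)[-j], function(k) {
      stats::sd(logq[j, ] - logq[k, ])
    }, numeric(1))
    m[j] <- mean(v)
  }
  names(m) <- rownames(logq)
  m
}

#' geNorm expression-stability analysis
#'
#' Pairwise variation `V_jk` is the standard deviation over samples of
#' `log2(Q_j / Q_k)`; a gene's `M` is the mean of `V_jk` over all
#' partners, lower meaning more stable.  The iterative mode repeatedly
#' removes the highest-`M` gene and recomputes until two genes remain;
#' the ranking is the reverse exclusion order, with the final two genes
#' tied at rank 1.5 (the exclusion step cannot separate them).
#'
#' @param q a [to_quantities()] result.
#' @return list with `m` (full-panel M per gene), `rank` (exclusion-order
#'   rank), `exclusion_order` (first-excluded first) and `final_pair`.
#' @export
genorm <- function(q) {
  stopifnot(inherits(q, "quantity_matrix"))
  logq <- log2(q$q)
  n <- nrow(logq)
  if (n < 2L) stop("geNorm needs at least 2 genes", call. = FALSE)
  m_full <- genorm_m_values(logq)
  genes <- rownames(logq)

  excluded <- character(0)
  remaining <- genes
  while (length(remaining) > 2L) {
    m <- genorm_m_values(logq[remaining, , drop = FALSE])
    worst <- names(m)[order(-m, names(m))][1L]   # ties: first gene id
    excluded <- c(excluded, worst)
    remaining <- setdiff(remaining, worst)
  }
  rk <- stats::setNames(numeric(n), genes)
  rk[remaining] <- 1.5
  if (length(excluded) > 0L) {
    rk[excluded] <- seq(n, 3L)
  }
  if (n == 2L) rk[] <- 1.5
  list(m = m_full, rank = rk[genes], exclusion_order = excluded,
       final_pair = remaining)
}

#' geNorm pairwise-variation series V(n/n+1)
#'
#' `NF_n` per sample is the geometric mean of the quantities of the `n`
#' most stable genes; `V_n` is the SD over samples of
#' `log2(NF_n / NF_(n+1))`.  Used to decide how many reference genes a
#' normalization factor needs.
#'
#' @param q a [to_quantities()] result.
#' @param ranked_genes genes ordered most stable first (e.g. by geNorm
#'   exclusion rank); needs at least 3.
#' @return named numeric vector `V2/3`, `V3/4`, ...
#' @export
genorm_pairwise_v <- function(q, ranked_genes) {
  stopifnot(inherits(q, "quantity_matrix"))
  if (length(ranked_genes) < 3L) {
    stop("pairwise V needs at least 3 ranked genes", call. = FALSE)
  }
  if (!all(ranked_genes %in% rownames(q$q))) {
    stop("ranked_genes not all present in the quantity matrix", call. = FALSE)
  }
  logq <- log2(q$q[ranked_genes, , drop = FALSE])
  nf_log <- function(n) colMeans(logq[seq_len(n), , drop = FALSE])
  ns <- seq(2L, length(ranked_genes) - 1L)
  v <- vapply(ns, function(n) stats::sd(nf_log(n) - nf_log(n + 1L)),
              numeric(1))
  names(v) <- sprintf("V%d/%d", ns, ns + 1L)
  v
}

# NormFinder variance components for one group's sample-centered data
# (genes x samples): unbiased intra-group variance estimates.  With k
# genes, centering mixes the genes' residuals, so the naive per-gene
# variance s2 is corrected by the pooled sum:
#   sigma2_i = k/(k-2) * (s2_i - sum(s2)/(k*(k-1))),  clamped at 0.
# Requires k >= 3 (the k-2 denominator is why 2 genes are rejected).
normfinder_group_var <- function(z) {
  k <- nrow(z)
  s2 <- apply(z, 1L, stats::var)
  pmax(0, k / (k - 2) * (s2 - sum(s2) / (k * (k - 1))))
}

#' NormFinder stability values
#'
#' Model-based stability on `y = log2(Q)`.  Each sample is centered by
#' its across-gene mean (removing the shared loading component), then
#' per gene and group the mean and the bias-corrected intra-group
#' variance are estimated.  Inter-group differences `d_ig` (the gene's
#' group mean minus its across-group average) are shrunken toward zero in
#' proportion to their sampling variance, and the stability value is the
#' mean over groups of `|d~_ig| + sqrt(sigma2_ig / n_g)` — inter-group
#' bias plus intra-group uncertainty, lower meaning more stable.  With a
#' single group the value degenerates to the SD of the gene's
#' sample-centered values.
#'
#' @param q a [to_quantities()] result; `q$groups` supplies the group
#'   factor (treatment by default).  At least 3 genes and 2 samples per
#'   group are required.
#' @return named numeric vector of stability values (rho), one per gene.
#' @export
normfinder <- function(q) {
  stopifnot(inherits(q, "quantity_matrix"))
  y <- log2(q$q)
  k <- nrow(y)
  if (k < 3L) {
    stop("NormFinder needs at least 3 genes (sample-centering leaves ",
         "antisymmetric residuals with 2)", call. = FALSE)
  }
  grp <- droplevels(as.factor(q$groups))
  if (min(table(grp)) < 2L) {
    stop("every group needs at least 2 samples", call. = FALSE)
  }
  z <- sweep(y, 2L, colMeans(y))          # sample centering
  genes <- rownames(y)
  G <- nlevels(grp)

  if (G == 1L) {
    rho <- apply(z, 1L, stats::sd)
    names(rho) <- genes
    return(rho)
  }

  a <- matrix(NA_real_, k, G, dimnames = list(genes, levels(grp)))
  sig2 <- a
  n_g <- table(grp)
  for (g in levels(grp)) {
    zg <- z[, grp == g, drop = FALSE]
    a[, g] <- rowMeans(zg)
    sig2[, g] <- normfinder_group_var(zg)
  }
  d <- a - rowMeans(a)
  cmat <- sweep(sig2, 2L, as.numeric(n_g), "/")
  # shrinkage scale for the inter-group differences; d has (k-1)(G-1)
  # free entries because it is doubly centered
  gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(cmat))
  dshrunk <- if (gamma2 == 0) d * 0 else d * gamma2 / (gamma2 + cmat)
  rho <- rowMeans(abs(dshrunk) + sqrt(cmat))
  names(rho) <- genes
  rho
}

#' BestKeeper descriptive statistics
#'
#' Per gene over the tissue's samples: the standard deviation of raw Cq
#' (the ranking statistic; higher SD = less stable), the coefficient of
#' variation `CV% = 100 * SD / mean`, and the Pearson correlation of the
#' gene's Cq with the BestKeeper index (the per-sample geometric mean of
#' all candidates' Cq; reported, not ranked on).  The original tool's
#' mean-absolute-deviation variant is available via `stat = "mad"`.
#'
#' @param table a [cq_table()].
#' @param tissue tissue to subset to, or `NULL`.
#' @param stat `"sd"` (sample SD, default) or `"mad"` (mean absolute
#'   deviation from the mean).
#' @param drop_incomplete_samples see [to_quantities()].
#' @return data.frame with columns `gene`, `sd`, `cv_pct`, `index_r`;
#'   `index_r` is `NA` when the correlation is undefined.
#' @export
bestkeeper <- function(table, tissue = NULL, stat = c("sd", "mad"),
                       drop_incomplete_samples = FALSE) {
  stopifnot(inherits(table, "cq_table"))
  stat <- match.arg(stat)
  cm <- cq_matrix(table, tissue = tissue,
                  drop_incomplete_samples = drop_incomplete_samples)
  m <- cm$cq
  disp <- switch(stat,
                 sd = apply(m, 1L, stats::sd),
                 mad = apply(m, 1L, function(v) mean(abs(v - mean(v)))))
  cv <- 100 * disp / rowMeans(m)
  index <- apply(m, 2L, geo_mean)
  index_r <- apply(m, 1L, function(v) {
    if (stats::sd(v) == 0 || stats::sd(index) == 0) NA_real_
    else stats::cor(v, index)
  })
  data.frame(gene = rownames(m), sd = disp, cv_pct = cv, index_r = index_r,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Comparative delta-Ct stability
#'
#' For every gene pair, the SD over samples of the per-sample Cq
#' difference; a gene's statistic is the mean of these SDs over all its
#' partners, lower meaning more stable.  With all efficiencies equal to
#' 2 this equals the geNorm M value exactly.
#'
#' @inheritParams bestkeeper
#' @return named numeric vector of mean pairwise SDs, one per gene.
#' @export
delta_ct <- function(table, tissue = NULL, drop_incomplete_samples = FALSE) {
  stopifnot(inherits(table, "cq_table"))
  cm <- cq_matrix(table, tissue = tissue,
                  drop_incomplete_samples = drop_incomplete_samples)
  m <- cm$cq
  if (nrow(m) < 2L) stop("delta-Ct needs at least 2 genes", call. = FALSE)
  n <- nrow(m)
  out <- numeric(n)
  for (j in seq_len(n)) {
    out[j] <- mean(vapply(seq_len(n)[-j], function(k) {
      stats::sd(m[j, ] - m[k, ])
    }, numeric(1)))
  }
  names(out) <- rownames(m)
  out
}

#' Geometric-mean comprehensive rank
#'
#' Combines per-method ranks the RefFinder way: a gene's comprehensive
#' value is the geometric mean of its ranks across methods.  The final
#' ordering is ascending, ties broken by the mean z-score of the raw
#' stability values (when supplied) and then by gene id.
#'
#' @param ranks named list of per-method rank vectors (1 = most stable),
#'   all over the same gene set; tied ranks may be fractional.
#' @param values optional named list of raw stability-value vectors
#'   (same methods/genes), used only for tie-breaking.
#' @return data.frame with `gene`, one `rank_<method>` column per method,
#'   `comprehensive` (geometric-mean rank) and `final_rank` (ordering
#'   1..n).
#' @export
comprehensive_rank <- function(ranks, values = NULL) {
  if (length(ranks) < 2L) stop("need at least 2 methods", call. = FALSE)
  genes <- sort(names(ranks[[1L]]))
  for (m in names(ranks)) {
    if (!setequal(names(ranks[[m]]), genes)) {
      stop(msg("method '", m, "' covers a different gene set"), call. = FALSE)
    }
  }
  rmat <- vapply(ranks, function(r) r[genes], numeric(length(genes)))
  if (is.null(dim(rmat))) rmat <- matrix(rmat, nrow = 1L,
                                         dimnames = list(genes, names(ranks)))
  comp <- apply(rmat, 1L, function(r) exp(mean(log(r))))

  tie_z <- rep(0, length(genes))
  if (!is.null(values)) {
    zmat <- vapply(values, function(v) {
      v <- v[genes]
      s <- stats::sd(v)
      if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }, numeric(length(genes)))
    if (is.null(dim(zmat))) zmat <- matrix(zmat, nrow = length(genes))
    tie_z <- rowMeans(zmat)
  }
  ord <- order(comp, tie_z, genes)
  final <- integer(length(genes))
  final[ord] <- seq_along(genes)

  out <- data.frame(gene = genes, rmat, comprehensive = comp,
                    final_rank = final, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[seq_along(ranks) + 1L] <- paste0("rank_", names(ranks))
  out
}

#' Rank reference-gene stability in one tissue
#'
#' Runs the selected stability methods on one tissue's samples (pooling
#' varieties and treatments, as the per-tissue panels do), assembles
#' per-method values and ranks, and combines them into the
#' geometric-mean comprehensive rank.  Technical replicates are
#' aggregated automatically when present.
#'
#' @param table a [cq_table()].
#' @param tissue tissue to analyse, or `NULL` for all samples.
#' @param methods subset of `c("genorm", "normfinder", "bestkeeper",
#'   "deltact")` (all four by default).
#' @param genorm_rank_basis what the geNorm rank column is based on:
#'   `"m"` (default) ranks genes by their full-panel M value, the basis
#'   of the per-tissue M charts and of RefFinder's geNorm step;
#'   `"exclusion"` uses the reverse iterative-exclusion order with the
#'   final pair tied at 1.5.  The exclusion order is sensitive to
#'   co-regulated gene clusters (see the methods vignette).
#' @param efficiency default amplification efficiency for
#'   [to_quantities()].
#' @param bestkeeper_stat passed to [bestkeeper()].
#' @param drop_incomplete_samples see [to_quantities()].
#' @return an object of class `stability_report`: a data.frame with one
#'   row per gene — per-method value and rank columns, `comprehensive`
#'   and `final_rank` — ordered by comprehensive rank (ties by gene id);
#'   attributes `tissue` and `methods`.
#' @export
rank_stability <- function(table, tissue = NULL,
                           methods = c("genorm", "normfinder",
                                       "bestkeeper", "deltact"),
                           genorm_rank_basis = c("m", "exclusion"),
                           efficiency = 2,
                           bestkeeper_stat = c("sd", "mad"),
                           drop_incomplete_samples = FALSE) {
  stopifnot(inherits(table, "cq_table"))
  known <- c("genorm", "normfinder", "bestkeeper", "deltact")
  bad <- setdiff(methods, known)
  if (length(bad) > 0L) {
    stop(msg("unknown stability method(s): ", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (length(methods) < 2L) stop("need at least 2 methods", call. = FALSE)
  genorm_rank_basis <- match.arg(genorm_rank_basis)
  bestkeeper_stat <- match.arg(bestkeeper_stat)
  if (anyDuplicated(table$records[, c("gene", "sample_id")])) {
    table <- aggregate_tech_reps(table)
  }

  values <- list()
  ranks <- list()
  if ("genorm" %in% methods || "normfinder" %in% methods) {
    q <- to_quantities(table, tissue = tissue, efficiency = efficiency,
                       drop_incomplete_samples = drop_incomplete_samples)
  }
  if ("genorm" %in% methods) {
    gn <- genorm(q)
    values$genorm <- gn$m
    ranks$genorm <- switch(genorm_rank_basis,
                           m = rank(gn$m, ties.method = "average"),
                           exclusion = gn$rank)
  }
  if ("normfinder" %in% methods) {
    nf <- normfinder(q)
    values$normfinder <- nf
    ranks$normfinder <- rank(nf, ties.method = "average")
  }
  if ("bestkeeper" %in% methods) {
    bk <- bestkeeper(table, tissue = tissue, stat = bestkeeper_stat,
                     drop_incomplete_samples = drop_incomplete_samples)
    values$bestkeeper <- stats::setNames(bk$sd, bk$gene)
    ranks$bestkeeper <- rank(values$bestkeeper, ties.method = "average")
  }
  if ("deltact" %in% methods) {
    dc <- delta_ct(table, tissue = tissue,
                   drop_incomplete_samples = drop_incomplete_samples)
    values$deltact <- dc
    ranks$deltact <- rank(dc, ties.method = "average")
  }

  comp <- comprehensive_rank(ranks, values)
  genes <- comp$gene
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  col_for <- c(genorm = "genorm_m", normfinder = "normfinder_rho",
               bestkeeper = "bestkeeper_sd", deltact = "deltact_meansd")
  for (m in names(values)) {
    out[[col_for[[m]]]] <- unname(values[[m]][genes])
    out[[paste0(m, "_rank")]] <- unname(ranks[[m]][genes])
  }
  out$comprehensive <- comp$comprehensive
  out$final_rank <- comp$final_rank
  out <- out[order(out$final_rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, tissue = if (is.null(tissue)) NA_character_ else tissue,
            methods = names(values), class = c("stability_report",
                                               "data.frame"))
}
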
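# The five-stage screening cascade.

test_that("abundance filter compares gene means to the dataset grand mean", {
  # grand mean 10.0 -> threshold 7.0: 7.1 passes, 6.9 fails
  vals <- matrix(rep(c(7.1, 6.9, 16.0, 10.0), each = 4), nrow = 4,
                 byrow = TRUE,
                 dimnames = list(c("hi", "lo", "big", "ten"), NULL))
  p <- panel_from_matrix(vals, treatment = rep(c("CK", "salt"), each = 2))
  expect_equal(mean(p$fpkm), 10)
  ab <- abundance_filter(p, screen_criteria())
  expect_identical(unname(ab[, 1]), c(TRUE, FALSE, TRUE, TRUE))

  # an identically-zero gene always fails
  zvals <- matrix(rep(c(0, 20), each = 4), nrow = 2, byrow = TRUE,
                  dimnames = list(c("zero", "on"), NULL))
  zp <- panel_from_matrix(zvals, treatment = rep(c("CK", "salt"), each = 2))
  expect_false(abundance_filter(zp)["zero", 1])
})

test_that("abundance filter matches a brute-force recomputation", {
  set.seed(21)
  sim <- simulate_fpkm_panel(simulation_design(seed = 21, n_datasets = 3,
                                               n_background_genes = 10))
  p <- sim$panel
  ab <- abundance_filter(p)
  for (d in unique(p$samples$dataset_id)) {
    sub <- p$fpkm[, p$samples$dataset_id == d]
    expect_identical(unname(ab[, d]),
                     unname(rowMeans(sub) > 0.70 * mean(sub)))
  }
  expect_error(abundance_filter(panel_from_matrix(
    matrix(0, 2, 4), treatment = rep(c("CK", "salt"), each = 2))),
    "all-zero")
})

test_that("ratio filter demands every group mean within the window", {
  # group means 9 / 10 / 11 around gene mean 10 -> ratios 0.9, 1.0, 1.1
  vals <- rbind(ok = rep(c(9, 10, 11), each = 2),
                edge = rep(c(13, 10, 7), each = 2))
  p <- panel_from_matrix(vals, treatment = rep(c("CK", "salt", "drought"),
                                               each = 2))
  ra <- ratio_window_filter(p)
  expect_true(ra["ok", 1])
  expect_false(ra["edge", 1])       # 13/10 = 1.30 is outside 0.75-1.25

  # brute-force check on a random panel
  set.seed(9)
  sim <- simulate_fpkm_panel(simulation_design(seed = 9, n_datasets = 2,
                                               n_background_genes = 6))
  ra2 <- ratio_window_filter(sim$panel)
  s <- sim$panel$samples
  for (d in unique(s$dataset_id)) {
    idx <- s$dataset_id == d
    sub <- sim$panel$fpkm[, idx]
    grp <- interaction(s$variety[idx], s$tissue[idx], s$treatment[idx],
                       drop = TRUE, lex.order = TRUE)
    for (g in rownames(sub)) {
      gm <- vapply(levels(grp), function(l) mean(sub[g, grp == l]),
                   numeric(1))
      expect_identical(unname(ra2[g, d]),
                       all(gm / mean(sub[g, ]) >= 0.75 &
                             gm / mean(sub[g, ]) <= 1.25))
    }
  }
})

test_that("ANOVA filter honors the degenerate-variance conventions", {
  vals <- rbind(flat = c(5, 5, 5, 5),     # identical everywhere -> p = 1
                det  = c(5, 5, 9, 9))     # differing, zero variance -> p = 0
  p <- panel_from_matrix(vals, treatment = rep(c("CK", "salt"), each = 2))
  an <- anova_filter(p)
  expect_equal(unname(an$p["flat", 1]), 1)
  expect_equal(unname(an$p["det", 1]), 0)
  expect_true(an$pass["flat", 1])
  expect_false(an$pass["det", 1])
})

test_that("ANOVA p agrees with the textbook F formula on a random layout", {
  set.seed(13)
  for (rep_i in 1:20) {
    y <- rnorm(12)
    grp <- factor(rep(c("a", "b", "c"), each = 4))
    gm <- tapply(y, grp, mean)
    ssb <- sum(4 * (gm - mean(y))^2)
    ssw <- sum((y - gm[grp])^2)
    f <- (ssb / 2) / (ssw / 9)
    p_ref <- pf(f, 2, 9, lower.tail = FALSE)
    expect_equal(refstab:::oneway_anova_p(y, grp), p_ref, tolerance = 1e-9)
  }
})

test_that("presence counting tallies datasets passing all three filters", {
  set.seed(4)
  sim <- simulate_fpkm_panel(simulation_design(seed = 4, n_datasets = 4,
                                               n_background_genes = 6))
  p <- sim$panel
  ab <- abundance_filter(p); ra <- ratio_window_filter(p)
  an <- anova_filter(p)
  pres <- presence_count(ab, ra, an$pass)
  manual <- rowSums(ab & ra & an$pass, na.rm = TRUE)
  expect_identical(pres$presence_count, unname(manual))
  expect_identical(pres$kept, unname(manual >= 2))

  one <- presence_count(ab[, 1, drop = FALSE], ra[, 1, drop = FALSE],
                        an$pass[, 1, drop = FALSE])
  expect_true(all(!one$kept[one$presence_count < 2]))
})

test_that("correlation scoring follows the sign convention and the r^2 formula", {
  # profiles over 2 datasets x 3 treatments = 6 cells, 1 rep per cell
  # FPKM = 2^x - 1 so that the log2(FPKM + 1) profile is exactly x
  base <- c(1, 2, 3, 4, 5, 6)
  vals <- rbind(a = 2^base - 1, b = 2^(2 * base + 1) - 1,
                c = 2^rev(base) - 1)
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     dataset_id = rep(c("D1", "D2"), each = 3),
                     variety = "V1", tissue = "leaf",
                     treatment = rep(c("CK", "salt", "drought"), 2),
                     bio_rep = 1L)
  suppressWarnings(p <- expression_panel(vals, meta))
  cr <- correlation_rank(p, c("a", "b", "c"),
                         screen_criteria(corr_aggregate = "max"))
  # a and b are exactly proportional on the log scale -> r^2 = 1
  expect_equal(cr$correlation_score[cr$gene == "a"], 1, tolerance = 1e-9)
  # c is a's negation -> contributes 0, and c's best score comes from b
  prof <- refstab:::expression_profiles(p, c("a", "b", "c"))
  expect_equal(pearson_r_brute(prof[, "a"], prof[, "c"]), -1,
               tolerance = 1e-9)

  # brute-force r^2 on random profiles
  set.seed(77)
  sim <- simulate_fpkm_panel(simulation_design(seed = 77, n_datasets = 3,
                                               n_background_genes = 0))
  genes <- sim$panel$genes[1:4]
  pr <- refstab:::expression_profiles(sim$panel, genes)
  r_pkg <- cor(pr)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(r_pkg[i, j], pearson_r_brute(pr[, i], pr[, j]),
                 tolerance = 1e-9)
  }
})

test_that("a zero-variance profile scores 0 with a reason, not an error", {
  vals <- rbind(a = 2^c(1, 2, 3, 4, 5, 6), b = 2^c(2, 4, 6, 8, 10, 12),
                flat = rep(7, 6))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     dataset_id = rep(c("D1", "D2"), each = 3),
                     variety = "V1", tissue = "leaf",
                     treatment = rep(c("CK", "salt", "drought"), 2),
                     bio_rep = 1L)
  suppressWarnings(p <- expression_panel(vals, meta))
  cr <- correlation_rank(p, c("a", "b", "flat"))
  expect_equal(cr$correlation_score[cr$gene == "flat"], 0)
  expect_identical(cr$reason[cr$gene == "flat"], "zero_variance")
  expect_false(cr$selected[cr$gene == "flat"])
})

test_that("the full cascade recovers the planted candidate set", {
  sim <- simulate_fpkm_panel(simulation_design(seed = 101))
  rep <- screen_candidates(sim$panel)
  expect_setequal(rep$selected, sim$truth$stable_gene_ids)
  # intermediate bookkeeping is complete
  expect_identical(nrow(rep$per_dataset),
                   length(sim$panel$genes) * 6L)
  expect_true(all(rep$per_gene$presence_count[
    match(rep$selected, rep$per_gene$gene)] >= 2))
})

test_that("disabling every threshold selects all expressed genes", {
  sim <- simulate_fpkm_panel(simulation_design(seed = 55,
                                               n_background_genes = 0))
  loose <- screen_criteria(abundance_fraction = 0, ratio_low = 1e-9,
                           ratio_high = 1e9, anova_alpha = 0,
                           min_dataset_presence = 0,
                           corr_r2_threshold = 0, corr_alpha = 1)
  rep <- screen_candidates(sim$panel, loose)
  expect_setequal(rep$selected, sim$panel$genes)
})

test_that("an empty panel yields an empty report", {
  sim <- simulate_fpkm_panel(simulation_design(seed = 3, n_datasets = 2,
                                               n_background_genes = 0))
  empty <- expression_panel(sim$panel$fpkm[0, , drop = FALSE],
                            sim$panel$samples, genes = character(0))
  rep <- screen_candidates(empty)
  expect_identical(nrow(rep$per_gene), 0L)
  expect_identical(rep$selected, character(0))
})

test_that("loosening thresholds never shrinks the kept set (stage-wise)", {
  sim <- simulate_fpkm_panel(simulation_design(seed = 61))
  base <- screen_criteria()
  kept_under <- function(cr) {
    rep <- screen_candidates(sim$panel, cr)
    rep$per_gene$gene[rep$per_gene$kept]
  }
  kept0 <- kept_under(base)
  looser <- list(
    screen_criteria(abundance_fraction = 0.3),
    screen_criteria(ratio_low = 0.5, ratio_high = 1.5),
    screen_criteria(anova_alpha = 0.01),     # smaller alpha keeps more
    screen_criteria(min_dataset_presence = 1))
  for (cr in looser) {
    expect_true(all(kept0 %in% kept_under(cr)))
  }
  # at a fixed kept set, loosening the correlation thresholds can only
  # grow the selected set
  sel_strict <- screen_candidates(sim$panel, base)$selected
  sel_loose <- screen_candidates(
    sim$panel, screen_criteria(corr_r2_threshold = 0.5,
                               corr_alpha = 0.5))$selected
  expect_true(all(sel_strict %in% sel_loose))
})

test_that("gene and sample order do not affect screening decisions", {
  sim <- simulate_fpkm_panel(simulation_design(seed = 71, n_datasets = 3,
                                               n_background_genes = 8))
  p <- sim$panel
  set.seed(1)
  gi <- sample(length(p$genes)); si <- sample(nrow(p$samples))
  shuffled <- expression_panel(p$fpkm[gi, si], p$samples[si, ],
                               genes = p$genes[gi])
  a <- screen_candidates(p)
  b <- screen_candidates(shuffled)
  expect_identical(a$selected, b$selected)
  pa <- a$per_gene[order(a$per_gene$gene), ]
  pb <- b$per_gene[order(b$per_gene$gene), ]
  rownames(pa) <- rownames(pb) <- NULL
  expect_equal(pa, pb)
})

test_that("screen reports serialize with their criteria header", {
  sim <- simulate_fpkm_panel(simulation_design(seed = 2, n_datasets = 2,
                                               n_background_genes = 4))
  rep <- screen_candidates(sim$panel)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen_report(rep, path)
  lines <- readLines(path)
  expect_match(lines[2], "abundance_fraction=0.7")
  expect_match(lines[3], "corr_aggregate=median")
  back <- read.delim(path, comment.char = "#")
  expect_identical(nrow(back), nrow(rep$per_gene))
})
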
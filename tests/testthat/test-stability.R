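# The four stability algorithms and the comprehensive rank.

test_that("to_quantities applies Q = E^(minCq - Cq) per gene", {
  m <- rbind(g1 = c(24, 25, 26), g2 = c(30, 30, 30))
  tab <- cq_table_from_matrix(m)
  q <- to_quantities(tab, "leaf")
  expect_equal(unname(q$q["g1", ]), c(1, 0.5, 0.25))
  expect_equal(unname(q$q["g2", ]), c(1, 1, 1))
  expect_true(all(q$q > 0 & q$q <= 1))

  m2 <- rbind(g1 = c(24, 25), g2 = c(20, 21))
  tab2 <- cq_table(cq_table_from_matrix(m2)$records,
                   efficiencies = c(g1 = 1.9, g2 = 2))
  q2 <- to_quantities(tab2, "leaf")
  expect_equal(unname(q2$q["g1", ]), c(1, 1 / 1.9), tolerance = 1e-12)
})

test_that("to_quantities refuses incomplete grids unless told to drop", {
  m <- rbind(g1 = c(24, 25), g2 = c(30, 31))
  tab <- cq_table_from_matrix(m)
  tab$records <- tab$records[-2, ]    # drop g1 in s2
  expect_error(to_quantities(tab, "leaf"), "missing Cq")
  q <- to_quantities(tab, "leaf", drop_incomplete_samples = TRUE)
  expect_identical(ncol(q$q), 1L)
})

test_that("proportional genes have zero geNorm pairwise variation", {
  set.seed(5)
  base <- runif(8, 24, 30)
  m <- rbind(g1 = base, g2 = base + 3)   # Q proportional at E = 2
  q <- to_quantities(cq_table_from_matrix(m), "leaf")
  gn <- genorm(q)
  expect_equal(unname(gn$m), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(gn$rank), c(1.5, 1.5))
})

test_that("geNorm V equals the SD of Cq differences when E = 2", {
  set.seed(6)
  for (i in 1:10) {
    m <- random_cq_matrix(5, 8)
    q <- to_quantities(cq_table_from_matrix(m), "leaf")
    logq <- log2(q$q)
    for (j in 1:4) for (k in (j + 1):5) {
      v <- sd(logq[j, ] - logq[k, ])
      expect_equal(v, sd(m[k, ] - m[j, ]), tolerance = 1e-12)
    }
    # and M equals the brute-force double loop
    expect_equal(unname(genorm(q)$m), genorm_m_brute(logq),
                 tolerance = 1e-9)
  }
})

test_that("geNorm exclusion ranking orders by stepwise M removal", {
  # one clearly unstable gene among three stable ones
  set.seed(8)
  noise <- matrix(rnorm(4 * 10, 0, 0.05), 4)
  m <- rbind(25 + noise[1, ], 26 + noise[2, ], 27 + noise[3, ],
             25 + c(rep(0, 5), rep(3, 5)) + noise[4, ])
  rownames(m) <- c("s1", "s2", "s3", "bad")
  q <- to_quantities(cq_table_from_matrix(m), "leaf")
  gn <- genorm(q)
  expect_identical(gn$exclusion_order[1], "bad")
  expect_equal(unname(gn$rank["bad"]), 4)
  expect_setequal(names(gn$rank)[gn$rank == 1.5], setdiff(rownames(m), c("bad", gn$exclusion_order)))
})

test_that("pairwise V series is zero for identical genes and loading-invariant", {
  m <- matrix(rep(c(24, 26, 25, 27, 28), times = 4), nrow = 4, byrow = TRUE)
  rownames(m) <- paste0("g", 1:4)
  q <- to_quantities(cq_table_from_matrix(m), "leaf")
  v <- genorm_pairwise_v(q, paste0("g", 1:4))
  expect_equal(unname(v), c(0, 0), tolerance = 1e-12)
  expect_named(v, c("V2/3", "V3/4"))

  set.seed(10)
  m2 <- random_cq_matrix(5, 9)
  q2 <- to_quantities(cq_table_from_matrix(m2), "leaf")
  rk <- names(sort(genorm(q2)$m))
  v2 <- genorm_pairwise_v(q2, rk)
  # brute force from the definitions
  logq <- log2(q2$q[rk, ])
  for (n in 2:4) {
    nf_n <- apply(logq[1:n, , drop = FALSE], 2, mean)
    nf_n1 <- apply(logq[1:(n + 1), , drop = FALSE], 2, mean)
    expect_equal(unname(v2[sprintf("V%d/%d", n, n + 1)]),
                 sd(nf_n - nf_n1), tolerance = 1e-9)
  }
  # per-sample loading shifts cancel
  shift <- runif(9, -2, 2)
  q3 <- to_quantities(cq_table_from_matrix(sweep(m2, 2, -shift)), "leaf")
  expect_equal(genorm_pairwise_v(q3, rk), v2, tolerance = 1e-9)

  expect_error(genorm_pairwise_v(q2, rk[1:2]), "at least 3")
})

test_that("NormFinder gives rho = 0 to a gene equal to the sample mean", {
  set.seed(11)
  x <- rnorm(12, 0, 1)
  m <- rbind(g1 = 26 + x, g2 = 26 - x, g3 = rep(26, 12))
  tab <- cq_table_from_matrix(m, treatments = c("CK", "salt"))
  q <- to_quantities(tab, "leaf")
  rho <- normfinder(q)
  expect_equal(unname(rho["g3"]), 0, tolerance = 1e-9)
  expect_true(all(rho[c("g1", "g2")] > rho["g3"]))
})

test_that("single-group NormFinder equals the SD of sample-centered values", {
  set.seed(12)
  for (i in 1:10) {
    m <- random_cq_matrix(5, 8)
    q <- to_quantities(cq_table_from_matrix(m, treatments = "CK"), "leaf")
    rho <- normfinder(q)
    y <- log2(q$q)
    z <- sweep(y, 2, colMeans(y))
    expect_equal(unname(rho), unname(apply(z, 1, sd)), tolerance = 1e-9)
  }
})

test_that("NormFinder rejects too-few genes and singleton groups", {
  m <- random_cq_matrix(2, 6)
  q <- to_quantities(cq_table_from_matrix(m), "leaf")
  expect_error(normfinder(q), "at least 3 genes")
  m3 <- random_cq_matrix(4, 3)
  q3 <- to_quantities(cq_table_from_matrix(m3, treatments = c("CK", "CK", "salt")),
                      "leaf")
  expect_error(normfinder(q3), "at least 2 samples")
})

test_that("NormFinder ranks a group-shifted gene last", {
  hits <- 0L
  for (i in 1:200) {
    set.seed(5000 + i)
    m <- matrix(rnorm(4 * 8, 0, 0.1), 4) + 26
    m[4, 5:8] <- m[4, 5:8] + 1          # +1 cycle in the second group
    rownames(m) <- paste0("g", 1:4)
    q <- to_quantities(cq_table_from_matrix(m, treatments = rep(c("CK", "salt"), each = 4)[
      c(1:4, 5:8)]), "leaf")
    rho <- normfinder(q)
    hits <- hits + (names(which.max(rho)) == "g4")
  }
  expect_gte(hits / 200, 0.95)
})

test_that("BestKeeper reports SD, CV and index correlation", {
  m <- rbind(flat = rep(25, 2), var2 = c(20, 22))
  bk <- bestkeeper(cq_table_from_matrix(m), "leaf")
  expect_equal(bk$sd[bk$gene == "flat"], 0)
  expect_equal(bk$sd[bk$gene == "var2"], sqrt(2), tolerance = 1e-12)
  expect_true(is.na(bk$index_r[bk$gene == "flat"]))

  set.seed(14)
  m2 <- random_cq_matrix(5, 9)
  bk2 <- bestkeeper(cq_table_from_matrix(m2), "leaf")
  idx <- apply(m2, 2, function(v) exp(mean(log(v))))
  for (g in rownames(m2)) {
    expect_equal(bk2$sd[bk2$gene == g], sd(m2[g, ]), tolerance = 1e-12)
    expect_equal(bk2$cv_pct[bk2$gene == g], 100 * sd(m2[g, ]) / mean(m2[g, ]),
                 tolerance = 1e-12)
    expect_equal(bk2$index_r[bk2$gene == g], cor(m2[g, ], idx),
                 tolerance = 1e-12)
  }
  # mean-absolute-deviation variant
  bk3 <- bestkeeper(cq_table_from_matrix(m2), "leaf", stat = "mad")
  expect_equal(bk3$sd[bk3$gene == "G01"],
               mean(abs(m2["G01", ] - mean(m2["G01", ]))), tolerance = 1e-12)
})

test_that("delta-Ct equals geNorm M when E = 2 and matches its brute force", {
  set.seed(15)
  for (i in 1:10) {
    m <- random_cq_matrix(6, 10)
    tab <- cq_table_from_matrix(m)
    dc <- delta_ct(tab, "leaf")
    q <- to_quantities(tab, "leaf")
    expect_equal(unname(dc), unname(genorm(q)$m), tolerance = 1e-12)
    expect_equal(unname(dc), genorm_m_brute(m), tolerance = 1e-9)
  }
  # genes differing by a constant have zero pairwise SD
  m0 <- rbind(g1 = c(24, 25, 26), g2 = c(27, 28, 29))
  expect_equal(unname(delta_ct(cq_table_from_matrix(m0), "leaf")),
               c(0, 0), tolerance = 1e-12)
})

test_that("comprehensive rank is the geometric mean of method ranks", {
  r1 <- c(a = 1, b = 2, c = 3)
  out <- comprehensive_rank(list(m1 = r1, m2 = r1, m3 = r1, m4 = r1))
  expect_equal(out$comprehensive, c(1, 2, 3))

  r <- list(m1 = c(a = 1, b = 2), m2 = c(a = 2, b = 1),
            m3 = c(a = 4, b = 3), m4 = c(a = 2, b = 4))
  out2 <- comprehensive_rank(r)
  expect_equal(out2$comprehensive[out2$gene == "a"], 16^(1 / 4))

  set.seed(16)
  for (i in 1:10) {
    rks <- lapply(1:4, function(j) setNames(sample(5), letters[1:5]))
    names(rks) <- paste0("m", 1:4)
    out3 <- comprehensive_rank(rks)
    brute <- sapply(letters[1:5], function(g) {
      prod(sapply(rks, `[[`, g))^(1 / 4)
    })
    expect_equal(out3$comprehensive, unname(brute[out3$gene]),
                 tolerance = 1e-12)
  }
  expect_error(comprehensive_rank(list(m1 = c(a = 1), m2 = c(b = 1))),
               "different gene set")
  expect_error(comprehensive_rank(list(m1 = r1)), "at least 2 methods")
})

test_that("loading shifts leave ratio-based methods unchanged, not BestKeeper", {
  set.seed(17)
  m <- random_cq_matrix(6, 10)
  shift <- runif(10, -2, 2)
  m2 <- sweep(m, 2, -shift)            # add shift per sample
  tab <- cq_table_from_matrix(m, treatments = c("CK", "salt"))
  tab2 <- cq_table_from_matrix(m2, treatments = c("CK", "salt"))
  q <- to_quantities(tab, "leaf"); q2 <- to_quantities(tab2, "leaf")

  expect_equal(genorm(q2)$m, genorm(q)$m, tolerance = 1e-9)
  expect_equal(delta_ct(tab2, "leaf"), delta_ct(tab, "leaf"),
               tolerance = 1e-9)
  expect_equal(normfinder(q2), normfinder(q), tolerance = 1e-9)
  bk <- bestkeeper(tab, "leaf"); bk2 <- bestkeeper(tab2, "leaf")
  expect_gt(max(abs(bk2$sd - bk$sd)), 0.1)
})

test_that("rank_stability assembles tied, degenerate and permuted cases", {
  # all genes identical: every value 0, all ranks tied
  m <- matrix(rep(c(24, 25, 26, 27, 28, 29), times = 4), nrow = 4,
              byrow = TRUE, dimnames = list(paste0("g", 1:4), NULL))
  tab <- cq_table_from_matrix(m, treatments = c("CK", "salt"))
  rep0 <- rank_stability(tab, "leaf")
  expect_true(all(abs(rep0$genorm_m) < 1e-12))
  expect_true(all(abs(rep0$deltact_meansd) < 1e-12))
  expect_true(all(abs(rep0$normfinder_rho) < 1e-12))
  expect_equal(rep0$genorm_rank, rep(2.5, 4))
  expect_equal(rep0$deltact_rank, rep(2.5, 4))

  # permuting record order changes nothing
  sim <- simulate_cq_experiment(simulation_design(tissues = "leaf", seed = 18))
  set.seed(18)
  shuf <- sim$table
  shuf$records <- shuf$records[sample(nrow(shuf$records)), ]
  a <- rank_stability(sim$table, "leaf")
  b <- rank_stability(shuf, "leaf")
  expect_equal(as.data.frame(a), as.data.frame(b))

  expect_error(rank_stability(sim$table, "leaf", methods = "genorm"),
               "at least 2 methods")
  expect_error(rank_stability(sim$table, "leaf",
                              methods = c("genorm", "bogus")),
               "unknown stability method")
})

test_that("exclusion-based geNorm ranking is available as an option", {
  sim <- simulate_cq_experiment(simulation_design(tissues = "leaf", seed = 19))
  rep_m <- rank_stability(sim$table, "leaf")
  rep_ex <- rank_stability(sim$table, "leaf", genorm_rank_basis = "exclusion")
  q <- to_quantities(aggregate_tech_reps(sim$table), "leaf")
  gn <- genorm(q)
  expect_equal(setNames(rep_ex$genorm_rank, rep_ex$gene)[names(gn$rank)],
               gn$rank)
  expect_equal(setNames(rep_m$genorm_rank, rep_m$gene)[names(gn$m)],
               rank(gn$m))
})
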
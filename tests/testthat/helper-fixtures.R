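# Fixture builders shared across test files.  Everything is generated in
# code; nothing is read from disk unless a test writes it first.

# Build a cq_table from a genes x samples Cq matrix.  Samples are split
# evenly over `treatments` (in column order); one variety, one tissue,
# single technical replicate.
cq_table_from_matrix <- function(m, treatments = "CK", tissue = "leaf") {
  genes <- rownames(m)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(m)))
  ns <- ncol(m)
  trt <- rep(treatments, length.out = ns)
  sample_id <- sprintf("S%02d", seq_len(ns))
  recs <- expand.grid(gi = seq_along(genes), si = seq_len(ns))
  cq_table(data.frame(
    gene = genes[recs$gi],
    sample_id = sample_id[recs$si],
    variety = "V1",
    tissue = tissue,
    treatment = trt[recs$si],
    bio_rep = recs$si,
    tech_rep = 1L,
    cq = m[cbind(recs$gi, recs$si)],
    stringsAsFactors = FALSE))
}

# Random Cq matrix with gene/sample names, values in a qPCR-plausible
# window.
random_cq_matrix <- function(n_genes, n_samples, lo = 20, hi = 32) {
  m <- matrix(stats::runif(n_genes * n_samples, lo, hi), n_genes,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

# Minimal expression panel: one dataset unless meta overrides.  `values`
# is a genes x samples matrix; groups come from `treatment`.
panel_from_matrix <- function(values, treatment, variety = "V1",
                              tissue = "leaf", dataset_id = "DS01") {
  ns <- ncol(values)
  genes <- rownames(values)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  rownames(values) <- genes
  treatment <- rep(treatment, length.out = ns)
  meta <- data.frame(
    sample_id = sprintf("%s_S%02d", dataset_id, seq_len(ns)),
    dataset_id = dataset_id,
    variety = rep(variety, length.out = ns),
    tissue = rep(tissue, length.out = ns),
    treatment = treatment,
    bio_rep = stats::ave(seq_len(ns), treatment, FUN = seq_along),
    stringsAsFactors = FALSE)
  expression_panel(values, meta)
}

# Brute-force Pearson r from the covariance formula.
pearson_r_brute <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Brute-force geNorm M / comparative dCt statistic from the definitions.
genorm_m_brute <- function(logq) {
  n <- nrow(logq)
  vapply(seq_len(n), function(j) {
    mean(vapply(seq_len(n)[-j],
                function(k) stats::sd(logq[j, ] - logq[k, ]), numeric(1)))
  }, numeric(1))
}
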
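# ExpressionPanel: a genes x samples FPKM matrix plus per-sample design
# metadata, grouped into datasets.  The substrate of the screening cascade.

SAMPLE_META_COLS <- c("sample_id", "dataset_id", "variety", "tissue",
                      "treatment", "bio_rep")

#' Construct an expression panel
#'
#' Bundles a genes x samples FPKM matrix with its sample metadata and
#' validates the pair: non-negative FPKM, unique gene and sample ids,
#' matching dimensions.  Datasets that cannot support a one-way ANOVA
#' (fewer than two condition groups, or any group with fewer than two
#' replicates) are flagged with a warning and recorded in the
#' `anova_excluded` attribute; the ANOVA filter skips them.
#'
#' @param fpkm numeric matrix (genes x samples) of FPKM values; rownames
#'   are gene ids unless `genes` is given.
#' @param samples data.frame with columns `sample_id`, `dataset_id`,
#'   `variety`, `tissue`, `treatment`, `bio_rep`, one row per matrix
#'   column, in column order.
#' @param genes character vector of gene ids (defaults to
#'   `rownames(fpkm)`).
#' @return an object of class `expression_panel`: a list with elements
#'   `genes`, `samples`, `fpkm`.
#' @export
expression_panel <- function(fpkm, samples, genes = rownames(fpkm)) {
  fpkm <- as.matrix(fpkm)
  if (is.null(genes)) stop("gene ids are required (rownames or `genes`)", call. = FALSE)
  genes <- as.character(genes)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  missing_cols <- setdiff(SAMPLE_META_COLS, names(samples))
  if (length(missing_cols) > 0L) {
    stop(msg("sample metadata lacks column(s): ",
             paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  samples <- samples[, SAMPLE_META_COLS]
  samples$bio_rep <- as.integer(samples$bio_rep)
  if (any(is.na(samples$bio_rep)) || any(samples$bio_rep < 1L)) {
    stop("bio_rep must be a positive integer", call. = FALSE)
  }

  if (nrow(fpkm) != length(genes)) {
    stop("fpkm row count does not match gene list", call. = FALSE)
  }
  if (ncol(fpkm) != nrow(samples)) {
    stop("fpkm column count does not match sample metadata rows", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop(msg("duplicate gene id(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop(msg("duplicate sample_id(s): ",
             paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
                   collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(fpkm)) stop("FPKM matrix must be numeric", call. = FALSE)
  if (anyNA(fpkm)) stop("FPKM matrix contains missing values", call. = FALSE)
  neg <- which(fpkm < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(msg("negative FPKM for gene '", genes[neg[1L, 1L]],
             "' in sample '", samples$sample_id[neg[1L, 2L]], "'"),
         call. = FALSE)
  }
  dimnames(fpkm) <- list(genes, samples$sample_id)

  # Datasets unusable for ANOVA: < 2 condition groups or any group with
  # < 2 replicates.
  excluded <- character(0)
  for (d in unique(samples$dataset_id)) {
    sm <- samples[samples$dataset_id == d, , drop = FALSE]
    grp <- condition_groups(sm)
    if (nlevels(grp) < 2L || min(table(grp)) < 2L) {
      excluded <- c(excluded, d)
    }
  }
  if (length(excluded) > 0L) {
    warning(msg("dataset(s) excluded from ANOVA filtering (",
                "need >=2 condition groups with >=2 replicates): ",
                paste(excluded, collapse = ", ")), call. = FALSE)
  }

  structure(
    list(genes = genes, samples = samples, fpkm = fpkm),
    anova_excluded = excluded,
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat("expression_panel:", length(x$genes), "genes x",
      nrow(x$samples), "samples,",
      length(unique(x$samples$dataset_id)), "dataset(s)\n")
  invisible(x)
}

#' Read an expression panel from disk
#'
#' The expression file is a TSV/CSV whose first column holds gene ids and
#' whose remaining columns are samples; the metadata file is a CSV mapping
#' each sample column to its design factors.  Sample columns without
#' metadata, or metadata rows without a matching column, are rejected.
#'
#' @param path expression matrix file (TSV for `.tsv`/`.txt`, CSV
#'   otherwise).
#' @param meta_path sample metadata CSV with the columns of
#'   [expression_panel()].
#' @return an [expression_panel()].
#' @export
read_expression_panel <- function(path, meta_path) {
  expr <- utils::read.table(path, sep = sep_for(path), header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"", comment.char = "")
  if (ncol(expr) < 2L) stop("expression file needs a gene column plus >=1 sample column", call. = FALSE)
  genes <- as.character(expr[[1L]])
  mat <- as.matrix(expr[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("non-numeric or missing FPKM value in expression file", call. = FALSE)

  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SAMPLE_META_COLS, names(meta))
  if (length(missing_cols) > 0L) {
    stop(msg("metadata file lacks column(s): ",
             paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(colnames(mat), meta$sample_id)
  if (length(unknown) > 0L) {
    stop(msg("sample column(s) without metadata: ",
             paste(unknown, collapse = ", ")), call. = FALSE)
  }
  orphan <- setdiff(meta$sample_id, colnames(mat))
  if (length(orphan) > 0L) {
    stop(msg("metadata row(s) without a matching sample column: ",
             paste(orphan, collapse = ", ")), call. = FALSE)
  }
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  rownames(mat) <- genes
  expression_panel(mat, meta, genes = genes)
}

#' Write an expression panel to disk
#'
#' Inverse of [read_expression_panel()]: writes the FPKM matrix as a TSV
#' (gene ids in the first column, `gene_id`) and the sample metadata as a
#' CSV.  The round trip is lossless up to numeric printing precision
#' (full double precision is written).
#'
#' @param panel an [expression_panel()].
#' @param path,meta_path output file paths.
#' @return invisibly, `panel`.
#' @export
write_expression_panel <- function(panel, path, meta_path) {
  stopifnot(inherits(panel, "expression_panel"))
  df <- data.frame(gene_id = panel$genes,
                   format(panel$fpkm, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(panel$samples, meta_path, row.names = FALSE, quote = FALSE)
  invisible(panel)
}
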
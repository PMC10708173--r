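# CqTable: long-format quantification-cycle records with the experimental
# design factors, plus optional per-gene amplification efficiencies.

CQ_RECORD_COLS <- c("gene", "sample_id", "variety", "tissue", "treatment",
                    "bio_rep", "tech_rep", "cq")

#' Construct a Cq table
#'
#' Long-format RT-qPCR quantification cycles.  Every Cq must lie in
#' `(0, cq_ceiling]`; values at the ceiling mean "not detected" and are
#' rejected for reference-gene work (a reference must be expressed in
#' every sample).  The default ceiling of 44 cycles is the length of the
#' amplification program.
#'
#' @param records data.frame with columns `gene`, `sample_id`, `variety`,
#'   `tissue`, `treatment`, `bio_rep`, `tech_rep`, `cq` (`variety` is
#'   optional and defaults to a single level).
#' @param efficiencies optional named numeric vector of per-gene
#'   amplification efficiencies E (fold change per cycle; 2 = 100%).
#' @param cq_ceiling maximum admissible Cq, cycles.
#' @return an object of class `cq_table`: list with `records`,
#'   `efficiencies`, `cq_ceiling`.
#' @export
cq_table <- function(records, efficiencies = NULL, cq_ceiling = 44) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"variety" %in% names(records)) records$variety <- "V1"
  missing_cols <- setdiff(CQ_RECORD_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop(msg("Cq records lack column(s): ",
             paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  records <- records[, CQ_RECORD_COLS]
  records$cq <- as.numeric(records$cq)
  if (anyNA(records$cq)) {
    stop(msg("non-numeric Cq in row ", which(is.na(records$cq))[1L]),
         call. = FALSE)
  }
  bad <- which(records$cq <= 0 | records$cq > cq_ceiling)
  if (length(bad) > 0L) {
    stop(msg("Cq out of (0, ", cq_ceiling, "] in row ", bad[1L],
             " (gene '", records$gene[bad[1L]], "', cq = ",
             records$cq[bad[1L]], ")"), call. = FALSE)
  }
  for (col in c("bio_rep", "tech_rep")) {
    records[[col]] <- as.integer(records[[col]])
    if (anyNA(records[[col]]) || any(records[[col]] < 1L)) {
      stop(msg(col, " must be a positive integer"), call. = FALSE)
    }
  }
  if (!is.null(efficiencies)) {
    if (is.null(names(efficiencies)) || any(!is.finite(efficiencies)) ||
        any(efficiencies <= 1)) {
      stop("efficiencies must be a named numeric vector with values > 1",
           call. = FALSE)
    }
  }
  dup <- duplicated(records[, c("gene", "sample_id", "tech_rep")])
  if (any(dup)) {
    stop(msg("duplicate (gene, sample, tech_rep) record: gene '",
             records$gene[dup][1L], "', sample '",
             records$sample_id[dup][1L], "'"), call. = FALSE)
  }
  structure(list(records = records, efficiencies = efficiencies,
                 cq_ceiling = cq_ceiling),
            class = "cq_table")
}

#' @export
print.cq_table <- function(x, ...) {
  r <- x$records
  cat("cq_table:", nrow(r), "records,", length(unique(r$gene)), "genes,",
      length(unique(r$sample_id)), "samples\n")
  invisible(x)
}

#' Read a long-format Cq table
#'
#' Expects a CSV with one row per well: gene, sample id, design factors,
#' technical replicate index and Cq.  Header names can be remapped via
#' `col_map` when the exporting software uses different labels.
#' Technical replicates are kept as-is; see [aggregate_tech_reps()].
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping the canonical
#'   names (`gene`, `sample_id`, `variety`, `tissue`, `treatment`,
#'   `bio_rep`, `tech_rep`, `cq`) to the file's header names.
#' @param efficiencies,cq_ceiling passed to [cq_table()].
#' @return a [cq_table()].
#' @export
read_cq_table <- function(path, col_map = NULL, efficiencies = NULL,
                          cq_ceiling = 44) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df)) {
        stop(msg("mapped column '", col_map[[canon]], "' not in file"),
             call. = FALSE)
      }
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  cq_table(df, efficiencies = efficiencies, cq_ceiling = cq_ceiling)
}

#' Write a Cq table as CSV
#'
#' @param table a [cq_table()].
#' @param path output CSV path.
#' @return invisibly, `table`.
#' @export
write_cq_table <- function(table, path) {
  stopifnot(inherits(table, "cq_table"))
  df <- table$records
  df$cq <- format(df$cq, digits = 17, trim = TRUE, scientific = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(table)
}

#' Average technical replicates
#'
#' Collapses each (gene, sample) cell to the arithmetic mean Cq of its
#' technical replicates, the community default for triplicate designs;
#' `tech_rep` is set to 1 in the result.  No outlier rejection is applied.
#'
#' @param table a [cq_table()].
#' @return a [cq_table()] with one record per (gene, sample).
#' @export
aggregate_tech_reps <- function(table) {
  stopifnot(inherits(table, "cq_table"))
  r <- table$records
  key <- c("gene", "sample_id", "variety", "tissue", "treatment", "bio_rep")
  agg <- stats::aggregate(r["cq"], by = r[key], FUN = mean)
  agg$tech_rep <- 1L
  agg <- agg[order(agg$gene, agg$sample_id), c(key, "tech_rep", "cq")]
  rownames(agg) <- NULL
  cq_table(agg, efficiencies = table$efficiencies,
           cq_ceiling = table$cq_ceiling)
}

# Complete genes x samples Cq matrix for one tissue (after technical
# aggregation); errors on missing cells rather than imputing, unless
# drop_incomplete_samples is set, in which case samples lacking any gene
# are removed for all genes.
cq_matrix <- function(table, tissue = NULL, drop_incomplete_samples = FALSE) {
  r <- table$records
  if (!is.null(tissue)) {
    r <- r[r$tissue %in% tissue, , drop = FALSE]
    if (nrow(r) == 0L) stop(msg("no Cq records for tissue '", tissue, "'"), call. = FALSE)
  }
  if (anyDuplicated(r[, c("gene", "sample_id")])) {
    stop("multiple technical replicates present; call aggregate_tech_reps() first",
         call. = FALSE)
  }
  genes <- sort(unique(r$gene))
  samp <- unique(r[, c("sample_id", "variety", "tissue", "treatment", "bio_rep")])
  samp <- samp[order(samp$sample_id), , drop = FALSE]
  rownames(samp) <- NULL
  m <- matrix(NA_real_, nrow = length(genes), ncol = nrow(samp),
              dimnames = list(genes, samp$sample_id))
  m[cbind(match(r$gene, genes), match(r$sample_id, samp$sample_id))] <- r$cq
  if (anyNA(m)) {
    if (drop_incomplete_samples) {
      keep <- colSums(is.na(m)) == 0L
      if (!any(keep)) stop("no complete samples after dropping incomplete ones", call. = FALSE)
      m <- m[, keep, drop = FALSE]
      samp <- samp[keep, , drop = FALSE]
    } else {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(msg("missing Cq for gene '", genes[idx[1L]], "' in sample '",
               samp$sample_id[idx[2L]], "'"), call. = FALSE)
    }
  }
  list(cq = m, samples = samp)
}

#' Read a serial-dilution Cq series
#'
#' @param path CSV with columns `gene`, `log10_dilution`, `cq`.
#' @return data.frame with those three columns.
#' @export
read_dilution_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "log10_dilution", "cq")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop(msg("dilution file lacks column(s): ",
             paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$log10_dilution <- as.numeric(df$log10_dilution)
  df$cq <- as.numeric(df$cq)
  if (anyNA(df$log10_dilution) || anyNA(df$cq)) {
    stop("non-numeric value in dilution series", call. = FALSE)
  }
  df[, need]
}
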
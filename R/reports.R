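# Report writers/readers with fixed, documented column sets.

#' Write a stability report as TSV
#'
#' One row per gene, the per-method value and rank columns present in
#' the report, then `comprehensive` and `final_rank`; rows ordered by
#' comprehensive rank (ties by gene id).  Deterministic column and row
#' order; numbers are written at full double precision so the round trip
#' through [read_stability_report()] is lossless.
#'
#' @param report a [rank_stability()] result.
#' @param path output path.
#' @return invisibly, `report`.
#' @export
write_stability_report <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stability_report tissue=%s methods=%s",
                     attr(report, "tissue"),
                     paste(attr(report, "methods"), collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Read back a stability report TSV
#'
#' @param path a file written by [write_stability_report()].
#' @return a `stability_report` data.frame with `tissue` and `methods`
#'   attributes restored.
#' @export
read_stability_report <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# stability_report")) {
    stop("not a stability report file", call. = FALSE)
  }
  tissue <- sub(".*tissue=(\\S+).*", "\\1", header)
  methods <- strsplit(sub(".*methods=(\\S+).*", "\\1", header), ",")[[1L]]
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  structure(df, tissue = tissue, methods = methods,
            class = c("stability_report", "data.frame"))
}

#' Write a fold-change table as TSV
#'
#' @param fc a [relative_expression()] (or row-bound) table.
#' @param path output path.
#' @return invisibly, `fc`.
#' @export
write_fold_change <- function(fc, path) {
  utils::write.table(as.data.frame(fc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fc)
}
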
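METRICS_TABLE_VERSION <- "myeloparc-metrics-v1"

#' Write the long-format parcel metrics table as TSV
#'
#' A versioned header comment line precedes the column header.
#'
#' @param table a [parcel_metrics()]-style data frame.
#' @param path output `.tsv` path.
#' @return the path, invisibly.
#' @export
write_metrics_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", METRICS_TABLE_VERSION), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a parcel metrics TSV written by [write_metrics_tsv()]
#'
#' @param path the `.tsv` path.
#' @return data frame.
#' @export
read_metrics_tsv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, paste0("# ", METRICS_TABLE_VERSION)))
    stop(path, " lacks the ", METRICS_TABLE_VERSION, " header")
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a machine-readable statistics report as JSON
#'
#' @param anova an `anova_result` from [two_way_anova()].
#' @param posthoc a [posthoc_bonferroni()] table.
#' @param summary a [summary_report()] table.
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_stats_json <- function(anova, posthoc, summary, path) {
  jsonlite::write_json(
    list(anova = anova$factors, posthoc = posthoc, summary = summary),
    path, dataframe = "rows", digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
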
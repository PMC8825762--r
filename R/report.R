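# Report writers. NA policy: undefined values serialize as "NA" in TSV
# and null in JSON; percentages are rounded to 2 decimals at this
# boundary only (internal values keep full precision).

round2 <- function(x) ifelse(is.na(x), NA_real_, round(x, 2))

#' Write the per-gene outcomes of a comparison as TSV
#'
#' One row per reference gene: coordinates, category, matched prediction
#' id, coverage and signed 5'/3' deviations.
#'
#' @param report A `comparison_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_outcomes_tsv <- function(report, path) {
  go <- report$gene_outcomes
  go$coverage <- round(go$coverage, 4)
  write.table(go, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write the per-prediction outcomes of a comparison as TSV
#' @inheritParams write_gene_outcomes_tsv
#' @return `path`, invisibly.
#' @export
write_prediction_outcomes_tsv <- function(report, path) {
  write.table(report$prediction_outcomes, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Serialize a comparison report to JSON
#' @inheritParams write_gene_outcomes_tsv
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(detection_threshold = report$detection_threshold,
              gene_outcomes = report$gene_outcomes,
              prediction_outcomes = report$prediction_outcomes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a metrics bundle as long-form TSV
#'
#' Columns `tool`, `genome`, `metric`, `name`, `value` (2 decimals,
#' `NA` where undefined).
#'
#' @param bundle A `metrics_bundle`.
#' @param path Output path.
#' @param tool,genome Labels for the long-form columns.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(bundle, path, tool = "tool",
                              genome = "genome") {
  b <- unclass(bundle)
  df <- data.frame(tool = tool, genome = genome, metric = names(b),
                   name = unname(metric_labels()[names(b)]),
                   value = round2(as.numeric(b)), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write a metrics bundle (and optional secondary metrics) as JSON
#' @inheritParams write_metrics_tsv
#' @param secondary Optional `secondary_metrics` list.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(bundle, path, secondary = NULL) {
  obj <- list(primary = as.list(round2(unclass(bundle))))
  if (!is.null(secondary)) obj$secondary <- unclass(secondary)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a rank table as TSV
#'
#' The summed-rank ordering (best first) followed by the full long-form
#' per-metric ranks.
#'
#' @param rank_table A `rank_table` from [rank_tools()].
#' @param path Output path for the totals; per-metric ranks go to
#'   `<path>.detail.tsv`.
#' @return `path`, invisibly.
#' @export
write_rank_tsv <- function(rank_table, path) {
  write.table(rank_table$total, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  write.table(rank_table$ranks, paste0(path, ".detail.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
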
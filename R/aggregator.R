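# Aggregation of prediction sets: deduplicated union evaluated with the
# same comparison algorithm as a single tool.

#' Union of prediction sets from several tools
#'
#' Combines the sets into one annotation with duplicate CDSs (exact
#' identity tuples) collapsed but alternative predictions for the same
#' locus (different coordinates) all retained, ordered by position. Each
#' retained feature carries the set of contributing tool labels in the
#' `tools` metadata column.
#'
#' @param sets Named list of CDS annotations (`GRanges`), one per tool.
#' @return A list of class `aggregate_set` with `features` (the union
#'   `GRanges`, `tools` provenance column), `labels`, and `provenance`
#'   (feature id to character vector of labels).
#' @export
union_predictions <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)),
            all(nzchar(names(sets))))
  labels <- names(sets)
  lev <- Reduce(union, lapply(sets, GenomeInfoDb::seqlevels))
  all_gr <- do.call(c, lapply(labels, function(lb) {
    g <- sets[[lb]]
    GenomeInfoDb::seqlevels(g) <- lev
    S4Vectors::mcols(g) <- NULL
    S4Vectors::mcols(g)$source <- rep(lb, length(g))
    g
  }))
  ids <- feature_id(all_gr)
  prov <- lapply(split(as.character(S4Vectors::mcols(all_gr)$source), ids),
                 function(x) sort(unique(x)))
  uni <- sort_dedup(all_gr)
  uid <- feature_id(uni)
  S4Vectors::mcols(uni)$source <- rep("aggregate", length(uni))
  S4Vectors::mcols(uni)$tools <- vapply(prov[uid], paste, character(1),
                                        collapse = ",")
  structure(list(features = uni, labels = labels, provenance = prov[uid]),
            class = "aggregate_set")
}

#' Compare the union of several prediction sets against a reference
#'
#' Runs [match_annotations()] on the deduplicated union, so the result is
#' directly comparable with single-tool reports. For every detected gene
#' the report additionally records which member tools contributed the
#' winning prediction (`contributing_tools` column).
#'
#' @param reference Reference CDS annotation (`GRanges`).
#' @param sets Named list of prediction annotations, one per tool.
#' @param threshold Detection coverage threshold (default 0.75).
#' @param one_to_one Passed to [match_annotations()].
#' @return A `comparison_report` with an `aggregate` element holding the
#'   `aggregate_set`.
#' @export
aggregate_compare <- function(reference, sets, threshold = 0.75,
                              one_to_one = TRUE) {
  agg <- union_predictions(sets)
  report <- match_annotations(reference, agg$features, threshold = threshold,
                              one_to_one = one_to_one)
  prov_str <- vapply(agg$provenance, paste, character(1), collapse = ",")
  go <- report$gene_outcomes
  go$contributing_tools <- ifelse(is.na(go$prediction_id), NA_character_,
                                  unname(prov_str[go$prediction_id]))
  report$gene_outcomes <- go
  report$aggregate <- agg
  report
}

#' @export
print.aggregate_set <- function(x, ...) {
  cat(sprintf("Aggregate of %d tool(s): %s\n", length(x$labels),
              paste(x$labels, collapse = ", ")))
  cat(sprintf("  %d unique CDS features after deduplication\n",
              length(x$features)))
  invisible(x)
}
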
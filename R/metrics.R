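# Primary metrics M1-M12, secondary metric groups, and cross-genome
# rank totalling.
#
# Undefined values (e.g. precision with zero predictions) propagate as NA,
# never as zeros; report writers serialize them as "NA"/null.

#' Percentage difference of a predicted metric from a reference metric
#'
#' `100 * (predicted - reference) / reference`. Zero means no deviation;
#' the statistic is unbounded in both directions. Undefined when the
#' reference value is zero (`NA` with a warning).
#'
#' @param predicted_value,reference_value Numeric scalars (vectorized).
#' @return Numeric percent (full precision; round at reporting time).
#' @examples
#' percentage_difference(2073, 1251)  # 65.707...
#' @export
percentage_difference <- function(predicted_value, reference_value) {
  out <- ifelse(reference_value == 0, NA_real_,
                100 * (predicted_value - reference_value) / reference_value)
  if (anyNA(out) && any(reference_value == 0, na.rm = TRUE))
    warning("percentage difference undefined for zero reference value")
  out
}

metric_names <- function() paste0("m", 1:12)

#' Orientation of each primary metric for ranking
#'
#' `"higher"`: larger is better (M1, M2, M5, M10, M11); `"zero"`: closer
#' to zero is better (M3, M4, M8, M9); `"lower"`: smaller is better
#' (M6, M7, M12).
#'
#' @return Named character vector over `m1`..`m12`.
#' @export
metric_orientation <- function() {
  c(m1 = "higher", m2 = "higher", m3 = "zero", m4 = "zero", m5 = "higher",
    m6 = "lower", m7 = "lower", m8 = "zero", m9 = "zero",
    m10 = "higher", m11 = "higher", m12 = "lower")
}

#' Human-readable names of the primary metrics
#' @return Named character vector over `m1`..`m12`.
#' @export
metric_labels <- function() {
  c(m1 = "Percentage of Genes Detected",
    m2 = "Percentage of Predicted CDSs that Detected a Gene",
    m3 = "Percentage Difference of Number of Predicted CDSs",
    m4 = "Percentage Difference of Median Predicted CDS Length",
    m5 = "Percentage of Perfect Matches",
    m6 = "Median Start Difference of Matched Predicted CDSs",
    m7 = "Median Stop Difference of Matched Predicted CDSs",
    m8 = "Percentage Difference of Matched Overlapping Predicted CDSs",
    m9 = "Percentage Difference of Matched Short Predicted CDSs",
    m10 = "Precision",
    m11 = "Recall",
    m12 = "False Discovery Rate")
}

pctdiff_quiet <- function(p, r) {
  if (is.na(r) || r == 0) return(NA_real_)
  100 * (p - r) / r
}

#' Compute the twelve primary comparison metrics
#'
#' Counts come from the comparison report: a gene is detected when its
#' category is not `MISSED`; a prediction is a detector (true positive)
#' when it is credited with a gene; non-detector predictions are false
#' positives and missed genes false negatives. M6/M7 are medians of the
#' absolute codon deviation over matched genes with a nonzero start
#' (resp. stop) deviation, 0 when no such gene exists. M8/M9 compare, by
#' percentage difference, the number of detector predictions that are
#' overlapping/short against the number of reference genes with the same
#' property (set `m89_side = "gene"` to evaluate the property on the
#' matched genes instead). M5's denominator is the detected genes; set
#' `m5_all_genes = TRUE` for the all-genes variant.
#'
#' @param report A `comparison_report` from [match_annotations()].
#' @param reference,predictions The annotations the report was produced from.
#' @param short_threshold Short-CDS bound in nt (default 300, strict `<`).
#' @param m5_all_genes Use all genes as the M5 denominator (default FALSE).
#' @param m89_side `"prediction"` (default) or `"gene"`.
#' @return A named numeric vector `m1`..`m12` of class `metrics_bundle`
#'   (full precision; `NA` where undefined).
#' @export
compute_primary <- function(report, reference, predictions,
                            short_threshold = 300, m5_all_genes = FALSE,
                            m89_side = c("prediction", "gene")) {
  m89_side <- match.arg(m89_side)
  go <- report$gene_outcomes
  po <- report$prediction_outcomes
  n_genes <- nrow(go)
  n_pred <- nrow(po)
  detected <- sum(go$category != "MISSED")
  perfect <- sum(go$category == "PERFECT")
  detectors <- sum(!is.na(po$matched_gene))
  tp <- detectors
  fp <- n_pred - detectors
  fn <- n_genes - detected

  m <- stats::setNames(rep(NA_real_, 12), metric_names())
  if (n_genes > 0) m["m1"] <- 100 * detected / n_genes
  if (n_pred > 0) m["m2"] <- 100 * detectors / n_pred
  if (n_genes > 0) m["m3"] <- pctdiff_quiet(n_pred, n_genes)
  med_ref_len <- if (n_genes > 0)
    stats::median(GenomicRanges::width(reference)) else NA_real_
  med_pred_len <- if (n_pred > 0)
    stats::median(GenomicRanges::width(predictions)) else NA_real_
  if (!is.na(med_pred_len)) m["m4"] <- pctdiff_quiet(med_pred_len, med_ref_len)
  m5_denom <- if (m5_all_genes) n_genes else detected
  if (m5_denom > 0) m["m5"] <- 100 * perfect / m5_denom

  matched <- go[go$category != "MISSED", , drop = FALSE]
  nz_start <- abs(matched$start_diff_codons)[matched$start_diff_nt != 0]
  nz_stop <- abs(matched$stop_diff_codons)[matched$stop_diff_nt != 0]
  m["m6"] <- if (length(nz_start)) stats::median(nz_start) else 0
  m["m7"] <- if (length(nz_stop)) stats::median(nz_stop) else 0

  ref_olap <- overlapping_features(reference)
  ref_short <- sum(is_short(reference, short_threshold))
  if (m89_side == "prediction") {
    pred_olap <- overlapping_features(predictions)
    det_ids <- po$prediction_id[!is.na(po$matched_gene)]
    n_olap <- sum(det_ids %in% pred_olap)
    n_short <- sum(po$length_nt[!is.na(po$matched_gene)] < short_threshold)
  } else {
    det_genes <- matched$gene_id
    n_olap <- sum(det_genes %in% ref_olap)
    n_short <- sum(matched$length_nt < short_threshold)
  }
  m["m8"] <- pctdiff_quiet(n_olap, length(ref_olap))
  m["m9"] <- pctdiff_quiet(n_short, ref_short)

  if (tp + fp > 0) {
    m["m10"] <- 100 * tp / (tp + fp)
    m["m12"] <- 100 * fp / (tp + fp)
  }
  if (tp + fn > 0) m["m11"] <- 100 * tp / (tp + fn)
  structure(m, class = c("metrics_bundle", "numeric"))
}

#' @export
print.metrics_bundle <- function(x, ...) {
  lab <- metric_labels()
  for (nm in metric_names()) {
    v <- unclass(x)[[nm]]
    cat(sprintf("%-4s %-60s %s\n", toupper(nm), lab[[nm]],
                ifelse(is.na(v), "NA", sprintf("%.2f", v))))
  }
  invisible(x)
}

median_or_na <- function(x) if (length(x)) stats::median(x) else NA_real_

#' Secondary metric groups
#'
#' Partitions genes by match category (with `detected = PERFECT + PARTIAL`
#' reported jointly) and computes: median GC content and median length per
#' category; overlapping and short CDS counts on both sides plus the
#' matched subsets; start-codon usage of matched predictions and of all
#' reference genes; and the number of genes encompassed by a prediction
#' they are not credited to. Sequence-derived blocks (GC, codon usage)
#' require the genome and are `NULL` without it.
#'
#' @inheritParams compute_primary
#' @param genome Optional `DNAStringSet`.
#' @return A named list of class `secondary_metrics`.
#' @export
compute_secondary <- function(report, reference, predictions, genome = NULL,
                              short_threshold = 300) {
  go <- report$gene_outcomes
  po <- report$prediction_outcomes
  cats <- list(PERFECT = go$category == "PERFECT",
               PARTIAL = go$category == "PARTIAL",
               MISSED = go$category == "MISSED",
               detected = go$category != "MISSED")

  pred_olap_ids <- overlapping_features(predictions)
  ref_olap_ids <- overlapping_features(reference)
  det_pred_ids <- po$prediction_id[!is.na(po$matched_gene)]

  out <- list(
    overlapping_pred_count = length(pred_olap_ids),
    overlapping_ref_count = length(ref_olap_ids),
    matched_overlapping_count = sum(det_pred_ids %in% pred_olap_ids),
    short_pred_count = sum(is_short(predictions, short_threshold)),
    short_ref_count = sum(is_short(reference, short_threshold)),
    matched_short_count = sum(po$length_nt[!is.na(po$matched_gene)] <
                                short_threshold),
    length_by_category = lapply(cats, function(k) median_or_na(go$length_nt[k])),
    signed_start_diff_median = median_or_na(
      go$start_diff_codons[go$category != "MISSED" & !is.na(go$start_diff_nt)]),
    signed_stop_diff_median = median_or_na(
      go$stop_diff_codons[go$category != "MISSED" & !is.na(go$stop_diff_nt)]),
    gc_by_category = NULL,
    start_codon_usage_matched = NULL,
    start_codon_usage_reference = NULL,
    count_genes_encompassed = count_genes_encompassed(report, reference,
                                                      predictions)
  )
  if (!is.null(genome)) {
    gene_gc <- per_feature_gc(reference, genome)
    out$gc_by_category <- lapply(cats, function(k) median_or_na(gene_gc[k]))
    if (length(det_pred_ids)) {
      det_pred <- predictions[feature_id(predictions) %in% det_pred_ids]
      out$start_codon_usage_matched <- start_codon_tally(det_pred, genome)
    } else out$start_codon_usage_matched <- integer(0)
    out$start_codon_usage_reference <- if (length(reference))
      start_codon_tally(reference, genome) else integer(0)
  }
  structure(out, class = "secondary_metrics")
}

per_feature_gc <- function(annotation, genome) {
  if (length(annotation) == 0L) return(numeric(0))
  check_bounds(annotation, genome)
  chars <- as.character(genome)
  ctg <- as.character(GenomicRanges::seqnames(annotation))
  seqs <- substr(chars[ctg], GenomicRanges::start(annotation),
                 GenomicRanges::end(annotation))
  suppressWarnings(gc_content(seqs))
}

# genes fully contained in a prediction that is not the prediction they
# were credited to (the "mistakenly encompassed" situation)
count_genes_encompassed <- function(report, reference, predictions) {
  if (length(reference) == 0L || length(predictions) == 0L) return(0L)
  h <- harmonize_seqlevels(reference, predictions)
  hits <- GenomicRanges::findOverlaps(h$a, h$b, type = "within",
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(0L)
  gi <- S4Vectors::queryHits(hits)
  pid <- feature_id(predictions)[S4Vectors::subjectHits(hits)]
  own <- report$gene_outcomes$prediction_id[gi]
  foreign <- is.na(own) | own != pid
  length(unique(gi[foreign]))
}

# ---- rank totalling -------------------------------------------------------

#' Rank tools across genomes by summed metric ranks
#'
#' Accepts either a long-form data.frame with columns `tool`, `genome`,
#' `metric` (`m1`..`m12`), `value`, or a nested list
#' `tool -> genome -> metrics_bundle`. Per metric and genome, tools are
#' ranked by the metric's orientation (see [metric_orientation()]); ties
#' receive the average of the tied rank positions; undefined (`NA`)
#' values, including those of a tool missing a genome entirely, rank
#' worst. The summed rank orders the final table ascending (best first).
#'
#' @param bundles Long data.frame or nested list of bundles.
#' @return A list of class `rank_table` with `ranks` (long data.frame
#'   with a `rank` column) and `total` (data.frame `tool`, `total_rank`,
#'   ordered best first).
#' @export
rank_tools <- function(bundles) {
  df <- if (is.data.frame(bundles)) bundles else {
    do.call(rbind, lapply(names(bundles), function(tl) {
      do.call(rbind, lapply(names(bundles[[tl]]), function(gn) {
        b <- unclass(bundles[[tl]][[gn]])
        data.frame(tool = tl, genome = gn, metric = names(b),
                   value = as.numeric(b), stringsAsFactors = FALSE)
      }))
    }))
  }
  stopifnot(all(c("tool", "genome", "metric", "value") %in% names(df)))
  tools_ <- sort(unique(df$tool))
  grid <- expand.grid(tool = tools_, genome = sort(unique(df$genome)),
                      metric = intersect(metric_names(), unique(df$metric)),
                      stringsAsFactors = FALSE)
  df <- merge(grid, df, all.x = TRUE)  # missing combinations become NA
  orient <- metric_orientation()
  parts <- split(df, list(df$genome, df$metric), drop = TRUE)
  ranked <- do.call(rbind, lapply(parts, function(p) {
    o <- orient[[p$metric[1]]]
    score <- switch(o, higher = -p$value, zero = abs(p$value),
                    lower = p$value)
    score[is.na(score)] <- Inf
    # rank() places all Inf (undefined) values in an average-tied worst block
    p$rank <- rank(score, ties.method = "average")
    p
  }))
  rownames(ranked) <- NULL
  ranked <- ranked[order(ranked$tool, ranked$genome, ranked$metric), ]
  tot <- stats::aggregate(list(total_rank = ranked$rank),
                          by = list(tool = ranked$tool), FUN = sum)
  tot <- tot[order(tot$total_rank, tot$tool), ]
  rownames(tot) <- NULL
  structure(list(ranks = ranked, total = tot), class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat("Summed metric ranks (best first):\n")
  print(x$total, row.names = FALSE)
  invisible(x)
}
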
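# Gene-detection classification.
#
# A reference gene counts as detected when some prediction on the same
# strand is in the same reading frame and covers at least 75% of the
# gene's nucleotides (threshold configurable). The detected gene is a
# perfect match when start and stop coordinates agree exactly, otherwise
# a partial match (5'/3' elongation or truncation); everything else is
# missed. Each prediction may be credited with at most one gene: a long
# prediction encompassing several smaller in-frame genes detects only the
# one it deviates least from.

#' Are a gene and a prediction in compatible reading frames?
#'
#' True iff the strands are equal and the start coordinates are congruent
#' modulo 3 (equivalent to 3'-anchored congruence when both lengths are
#' codon multiples). Features on different contigs are never compatible.
#' Vectorized with recycling.
#'
#' @param gene,prediction `GRanges` of recyclable lengths.
#' @return Logical vector.
#' @export
frame_compatible <- function(gene, prediction) {
  n <- max(length(gene), length(prediction))
  if (n == 0L) return(logical(0))
  ig <- rep_len(seq_along(gene), n)
  ip <- rep_len(seq_along(prediction), n)
  same_ctg <- as.character(GenomicRanges::seqnames(gene))[ig] ==
    as.character(GenomicRanges::seqnames(prediction))[ip]
  same_str <- as.character(GenomicRanges::strand(gene))[ig] ==
    as.character(GenomicRanges::strand(prediction))[ip]
  cong <- (GenomicRanges::start(prediction)[ip] -
             GenomicRanges::start(gene)[ig]) %% 3L == 0L
  same_ctg & same_str & cong
}

#' Fraction of a gene covered by a prediction
#'
#' `overlap_length(gene, prediction) / length(gene)`, in `[0, 1]`,
#' computed regardless of frame (frame is a separate gate). Zero when the
#' contigs differ. Vectorized with recycling.
#'
#' @inheritParams frame_compatible
#' @return Numeric vector of fractions.
#' @export
coverage_fraction <- function(gene, prediction) {
  n <- max(length(gene), length(prediction))
  if (n == 0L) return(numeric(0))
  ig <- rep_len(seq_along(gene), n)
  overlap_length(gene, prediction) / GenomicRanges::width(gene)[ig]
}

#' Signed 5'/3' coordinate deviations in gene orientation
#'
#' Positive values are elongations of the prediction relative to the gene,
#' negative values truncations, both read 5' to 3' in gene orientation:
#' on the forward strand `start_diff = gene_start - pred_start` and
#' `stop_diff = pred_end - gene_end`; on the reverse strand
#' `start_diff = pred_end - gene_end` and `stop_diff = gene_start - pred_start`.
#'
#' @inheritParams frame_compatible
#' @return A data.frame with integer columns `start_diff_nt`, `stop_diff_nt`.
#' @export
signed_diffs <- function(gene, prediction) {
  n <- max(length(gene), length(prediction))
  if (n == 0L)
    return(data.frame(start_diff_nt = integer(0), stop_diff_nt = integer(0)))
  ig <- rep_len(seq_along(gene), n)
  ip <- rep_len(seq_along(prediction), n)
  gs <- as.character(GenomicRanges::strand(gene))[ig]
  ps <- as.character(GenomicRanges::strand(prediction))[ip]
  if (any(gs != ps)) stop("signed_diffs requires matching strands")
  g1 <- GenomicRanges::start(gene)[ig]; g2 <- GenomicRanges::end(gene)[ig]
  p1 <- GenomicRanges::start(prediction)[ip]
  p2 <- GenomicRanges::end(prediction)[ip]
  fwd <- gs == "+"
  data.frame(
    start_diff_nt = as.integer(ifelse(fwd, g1 - p1, p2 - g2)),
    stop_diff_nt = as.integer(ifelse(fwd, p2 - g2, g1 - p1))
  )
}

# Candidate table: for each (gene, prediction) pair passing the detection
# gate, the deviation key used for best-match selection and contention.
candidate_table <- function(reference, predictions, threshold) {
  h <- harmonize_seqlevels(reference, predictions)
  hits <- GenomicRanges::findOverlaps(h$a, h$b, ignore.strand = FALSE)
  gi <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  if (length(gi) == 0L)
    return(data.frame(gene = integer(0), pred = integer(0),
                      dev = integer(0), abs_sd = integer(0),
                      coverage = numeric(0), start_diff = integer(0),
                      stop_diff = integer(0)))
  ok_frame <- frame_compatible(reference[gi], predictions[pi])
  cov <- coverage_fraction(reference[gi], predictions[pi])
  keep <- ok_frame & cov >= threshold
  gi <- gi[keep]; pi <- pi[keep]; cov <- cov[keep]
  if (length(gi) == 0L)
    return(data.frame(gene = integer(0), pred = integer(0),
                      dev = integer(0), abs_sd = integer(0),
                      coverage = numeric(0), start_diff = integer(0),
                      stop_diff = integer(0)))
  d <- signed_diffs(reference[gi], predictions[pi])
  cand <- data.frame(
    gene = gi, pred = pi,
    dev = abs(d$start_diff_nt) + abs(d$stop_diff_nt),
    abs_sd = abs(d$start_diff_nt),
    coverage = cov,
    start_diff = d$start_diff_nt, stop_diff = d$stop_diff_nt
  )
  # deterministic candidate preference: smallest total deviation, then
  # smallest |start diff|, then leftmost prediction start, then shortest
  # prediction, then prediction index
  cand[order(cand$gene, cand$dev, cand$abs_sd,
             GenomicRanges::start(predictions)[cand$pred],
             GenomicRanges::width(predictions)[cand$pred], cand$pred), ]
}

#' Classify a single reference gene against a prediction set
#'
#' Candidate predictions are those on the same contig and strand, in frame
#' and covering at least `threshold` of the gene. With no candidate the
#' gene is `MISSED`; otherwise the candidate minimizing
#' `|start_diff| + |stop_diff|` is selected (ties: smaller `|start_diff|`,
#' then leftmost start, then shortest, then input order) and the gene is
#' `PERFECT` when both deviations are zero, else `PARTIAL`.
#'
#' @param gene A length-1 `GRanges`.
#' @param predictions A `GRanges` of candidate predictions.
#' @param threshold Detection coverage threshold in `(0, 1]` (default 0.75).
#' @return A one-row data.frame with columns `gene_id`, `category`,
#'   `prediction_id`, `coverage`, `start_diff_nt`, `stop_diff_nt`,
#'   `start_diff_codons`, `stop_diff_codons`.
#' @export
classify_gene <- function(gene, predictions, threshold = 0.75) {
  stopifnot(length(gene) == 1L, threshold > 0, threshold <= 1)
  cand <- candidate_table(gene, predictions, threshold)
  if (nrow(cand) == 0L) {
    return(data.frame(
      gene_id = feature_id(gene), category = "MISSED",
      prediction_id = NA_character_, coverage = NA_real_,
      start_diff_nt = NA_integer_, stop_diff_nt = NA_integer_,
      start_diff_codons = NA_real_, stop_diff_codons = NA_real_,
      stringsAsFactors = FALSE))
  }
  best <- cand[1, ]
  data.frame(
    gene_id = feature_id(gene),
    category = if (best$dev == 0L) "PERFECT" else "PARTIAL",
    prediction_id = feature_id(predictions[best$pred]),
    coverage = best$coverage,
    start_diff_nt = best$start_diff, stop_diff_nt = best$stop_diff,
    start_diff_codons = best$start_diff / 3,
    stop_diff_codons = best$stop_diff / 3,
    stringsAsFactors = FALSE)
}

#' Compare a full prediction set against a reference annotation
#'
#' Gene-centric assignment under the constraint that each prediction is
#' credited with at most one gene. Genes are processed in coordinate
#' order; contention for the same prediction is resolved in favour of the
#' gene with the smaller deviation key (total deviation, then
#' `|start_diff|`, then coordinate order), and the losing gene falls back
#' to its next-best candidate or `MISSED`. Fully deterministic for fixed
#' input. Set `one_to_one = FALSE` to allow a single prediction to detect
#' every gene it qualifies for (sensitivity analysis).
#'
#' @param reference Reference CDS annotation (`GRanges`).
#' @param predictions Prediction CDS annotation (`GRanges`).
#' @param threshold Detection coverage threshold (default 0.75).
#' @param one_to_one Enforce at-most-one gene per prediction (default TRUE).
#' @return A `comparison_report`: list with data.frames `gene_outcomes`
#'   (one row per reference gene) and `prediction_outcomes` (one row per
#'   prediction), plus the threshold used.
#' @export
match_annotations <- function(reference, predictions, threshold = 0.75,
                              one_to_one = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  reference <- sort_dedup(reference)
  predictions <- sort_dedup(predictions)
  extra_ctg <- setdiff(unique(as.character(GenomicRanges::seqnames(predictions))),
                       unique(as.character(GenomicRanges::seqnames(reference))))
  if (length(extra_ctg) && length(reference))
    warning("prediction contig(s) absent from reference (counted as ",
            "non-detectors): ", paste(extra_ctg, collapse = ", "))
  n_gene <- length(reference)
  n_pred <- length(predictions)
  cand <- candidate_table(reference, predictions, threshold)
  cand_by_gene <- split(seq_len(nrow(cand)), factor(cand$gene, levels = seq_len(n_gene)))

  assigned <- rep(NA_integer_, n_gene)   # row of `cand` chosen per gene
  if (one_to_one) {
    owner <- rep(0L, n_pred)             # gene currently holding a prediction
    owner_row <- rep(0L, n_pred)
    ptr <- rep(1L, n_gene)
    queue <- seq_len(n_gene)             # coordinate order
    better_than <- function(row_g, g, row_o, o) {
      kg <- c(cand$dev[row_g], cand$abs_sd[row_g], g)
      ko <- c(cand$dev[row_o], cand$abs_sd[row_o], o)
      diff <- kg - ko
      nz <- which(diff != 0)
      length(nz) > 0 && diff[nz[1]] < 0
    }
    while (length(queue)) {
      g <- queue[1]; queue <- queue[-1]
      rows <- cand_by_gene[[g]]
      repeat {
        if (ptr[g] > length(rows)) { assigned[g] <- NA_integer_; break }
        row <- rows[ptr[g]]
        ptr[g] <- ptr[g] + 1L
        p <- cand$pred[row]
        if (owner[p] == 0L) {
          owner[p] <- g; owner_row[p] <- row; assigned[g] <- row
          break
        }
        if (better_than(row, g, owner_row[p], owner[p])) {
          evicted <- owner[p]
          owner[p] <- g; owner_row[p] <- row; assigned[g] <- row
          assigned[evicted] <- NA_integer_
          queue <- c(queue, evicted)
          break
        }
      }
    }
  } else {
    first <- vapply(cand_by_gene, function(r)
      if (length(r)) r[1] else NA_integer_, integer(1))
    assigned <- first
  }

  gene_ids <- feature_id(reference)
  pred_ids <- feature_id(predictions)
  has <- !is.na(assigned)
  rows <- assigned[has]
  gene_outcomes <- data.frame(
    gene_id = gene_ids,
    contig = as.character(GenomicRanges::seqnames(reference)),
    start = GenomicRanges::start(reference),
    end = GenomicRanges::end(reference),
    strand = as.character(GenomicRanges::strand(reference)),
    length_nt = GenomicRanges::width(reference),
    category = "MISSED",
    prediction_id = NA_character_,
    coverage = NA_real_,
    start_diff_nt = NA_integer_, stop_diff_nt = NA_integer_,
    start_diff_codons = NA_real_, stop_diff_codons = NA_real_,
    stringsAsFactors = FALSE)
  if (any(has)) {
    gene_outcomes$category[has] <- ifelse(cand$dev[rows] == 0L, "PERFECT", "PARTIAL")
    gene_outcomes$prediction_id[has] <- pred_ids[cand$pred[rows]]
    gene_outcomes$coverage[has] <- cand$coverage[rows]
    gene_outcomes$start_diff_nt[has] <- cand$start_diff[rows]
    gene_outcomes$stop_diff_nt[has] <- cand$stop_diff[rows]
    gene_outcomes$start_diff_codons[has] <- cand$start_diff[rows] / 3
    gene_outcomes$stop_diff_codons[has] <- cand$stop_diff[rows] / 3
  }

  matched_gene <- rep(NA_character_, n_pred)
  if (any(has)) {
    detects <- stats::aggregate(
      list(gene = gene_ids[which(has)]),
      by = list(pred = cand$pred[rows]),
      FUN = function(x) paste(x, collapse = ","))
    matched_gene[detects$pred] <- detects$gene
  }
  prediction_outcomes <- data.frame(
    prediction_id = pred_ids,
    contig = as.character(GenomicRanges::seqnames(predictions)),
    start = GenomicRanges::start(predictions),
    end = GenomicRanges::end(predictions),
    strand = as.character(GenomicRanges::strand(predictions)),
    length_nt = GenomicRanges::width(predictions),
    source = if (n_pred && "source" %in% names(S4Vectors::mcols(predictions)))
      as.character(S4Vectors::mcols(predictions)$source) else
        rep(NA_character_, n_pred),
    matched_gene = matched_gene,
    stringsAsFactors = FALSE)

  structure(list(gene_outcomes = gene_outcomes,
                 prediction_outcomes = prediction_outcomes,
                 detection_threshold = threshold,
                 one_to_one = one_to_one),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  tab <- table(factor(x$gene_outcomes$category,
                      levels = c("PERFECT", "PARTIAL", "MISSED")))
  cat(sprintf("Comparison of %d predictions against %d reference genes ",
              nrow(x$prediction_outcomes), nrow(x$gene_outcomes)),
      sprintf("(coverage threshold %.2f)\n", x$detection_threshold))
  cat(sprintf("  perfect %d | partial %d | missed %d\n",
              tab["PERFECT"], tab["PARTIAL"], tab["MISSED"]))
  invisible(x)
}
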
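# GFF set operations: intersection of two annotations under the
# coverage/frame rule, and guarded addition of new CDSs to an existing
# annotation.

#' Intersection of two annotations under the detection rule
#'
#' Keeps the features of `a` for which at least one feature of `b` is
#' frame-compatible (same strand, start coordinates congruent mod 3;
#' disabled with `require_frame = FALSE`, in which case any strand
#' qualifies) and covers at least `min_coverage` of the `a` feature.
#' The kept features retain the `a`-side coordinates; `symmetric = TRUE`
#' additionally keeps the `b` features supported by `a` and returns the
#' union of both directions.
#'
#' @param a,b CDS annotations (`GRanges`).
#' @param min_coverage Coverage threshold in `(0, 1]` (default 0.75).
#' @param require_frame Require frame compatibility (default TRUE).
#' @param symmetric Also keep supported `b` features (default FALSE).
#' @return A sorted, deduplicated `GRanges`.
#' @export
gff_intersect <- function(a, b, min_coverage = 0.75, require_frame = TRUE,
                          symmetric = FALSE) {
  stopifnot(min_coverage > 0, min_coverage <= 1)
  keep_supported <- function(x, y) {
    if (length(x) == 0L || length(y) == 0L) return(x[integer(0)])
    h <- harmonize_seqlevels(x, y)
    hits <- GenomicRanges::findOverlaps(h$a, h$b,
                                        ignore.strand = !require_frame)
    xi <- S4Vectors::queryHits(hits)
    yi <- S4Vectors::subjectHits(hits)
    ok <- coverage_fraction(x[xi], y[yi]) >= min_coverage
    if (require_frame) ok <- ok & frame_compatible(x[xi], y[yi])
    x[sort(unique(xi[ok]))]
  }
  out <- keep_supported(a, b)
  if (symmetric) {
    h <- harmonize_seqlevels(out, keep_supported(b, a))
    out <- c(h$a, h$b)
  }
  sort_dedup(out)
}

#' Add new CDSs to an existing annotation with an overlap cap
#'
#' Returns the existing annotation plus every new feature whose overlap
#' with each existing feature is at most `overlap_allowance` nt (default
#' 50; features overlapping by more are removed). The overlap test is
#' strand-agnostic by default. `footprint = TRUE` instead caps the total
#' overlap of a new feature with the merged footprint of the existing
#' annotation. Added features carry `status = "added"` in their metadata.
#'
#' @param existing,new CDS annotations (`GRanges`).
#' @param overlap_allowance Maximum tolerated overlap in nt (default 50).
#' @param ignore_strand Compare overlaps across strands (default TRUE).
#' @param footprint Test against the merged existing footprint instead of
#'   per-feature maxima (default FALSE, the stricter per-feature rule).
#' @return A sorted, deduplicated `GRanges` containing all of `existing`.
#' @export
gff_add <- function(existing, new, overlap_allowance = 50,
                    ignore_strand = TRUE, footprint = FALSE) {
  stopifnot(overlap_allowance >= 0)
  if (length(new) == 0L) return(sort_dedup(existing))
  if (length(existing) == 0L) {
    out <- new
    S4Vectors::mcols(out)$status <- rep("added", length(out))
    return(sort_dedup(out))
  }
  target <- if (footprint)
    GenomicRanges::reduce(GenomicRanges::granges(existing),
                          ignore.strand = TRUE) else existing
  h <- harmonize_seqlevels(new, target)
  hits <- GenomicRanges::findOverlaps(h$a, h$b, ignore.strand = ignore_strand)
  ni <- S4Vectors::queryHits(hits)
  ei <- S4Vectors::subjectHits(hits)
  ol <- overlap_length(new[ni], target[ei])
  per_new <- if (footprint)
    tapply(ol, factor(ni, levels = seq_along(new)), sum) else
      tapply(ol, factor(ni, levels = seq_along(new)), max)
  per_new[is.na(per_new)] <- 0
  keep <- new[per_new <= overlap_allowance]
  # an identical copy of an existing feature overlaps it by its full
  # length, so duplicates are removed by the cap itself for any feature
  # longer than the allowance; identity-level dedup handles the rest
  S4Vectors::mcols(keep) <- S4Vectors::mcols(keep)[
    , intersect("source", names(S4Vectors::mcols(keep))), drop = FALSE]
  if (length(keep)) S4Vectors::mcols(keep)$status <- rep("added", length(keep))
  ex <- existing
  if (length(ex)) S4Vectors::mcols(ex)$status <- rep("existing", length(ex))
  hm <- harmonize_seqlevels(ex, keep)
  common <- intersect(names(S4Vectors::mcols(hm$a)), names(S4Vectors::mcols(hm$b)))
  S4Vectors::mcols(hm$a) <- S4Vectors::mcols(hm$a)[, common, drop = FALSE]
  S4Vectors::mcols(hm$b) <- S4Vectors::mcols(hm$b)[, common, drop = FALSE]
  sort_dedup(c(hm$a, hm$b))
}
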
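#' @importFrom methods is
#' @importFrom stats median runif rpois setNames
#' @importFrom utils head read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a CDS annotation
#'
#' An annotation is an ordered, deduplicated set of CDS intervals held as a
#' [GenomicRanges::GRanges] with 1-based inclusive coordinates, an explicit
#' strand (`+` or `-`) and a `source` metadata column naming the producing
#' tool (or `"reference"`). Feature identity is the tuple
#' (contig, start, end, strand); duplicates by identity are dropped and the
#' result is sorted by (contig, start, end, strand).
#'
#' @param contig Character vector of contig (sequence) identifiers.
#' @param start,end Integer vectors, 1-based inclusive, `1 <= start <= end`.
#' @param strand Character vector of `"+"` / `"-"`.
#' @param source Character scalar or vector labelling the producing tool.
#' @param attributes Optional data.frame of extra metadata columns (recycled
#'   checks apply).
#' @return A sorted, deduplicated `GRanges`.
#' @examples
#' cds_annotation("c1", c(10, 400), c(309, 702), c("+", "-"))
#' @export
cds_annotation <- function(contig, start, end, strand, source = "reference",
                           attributes = NULL) {
  n <- length(start)
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$source <- character(0)
    return(gr)
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-integer coordinates in annotation")
  if (any(start < 1L))
    stop("coordinates are 1-based; start must be >= 1")
  bad <- which(start > end)
  if (length(bad))
    stop(sprintf("start > end for feature %d (%s:%d-%d)",
                 bad[1], contig[bad[1]], start[bad[1]], end[bad[1]]))
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every CDS feature")
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr)$source <- rep_len(as.character(source), n)
  if (!is.null(attributes)) {
    stopifnot(nrow(attributes) == n)
    for (nm in names(attributes)) S4Vectors::mcols(gr)[[nm]] <- attributes[[nm]]
  }
  sort_dedup(gr)
}

#' Sort an annotation and drop identity-tuple duplicates
#'
#' Sorting is by (contig, start, end, strand) using character comparison of
#' contig names; `duplicated()` on a `GRanges` compares exactly the identity
#' tuple (seqnames, start, end, strand), never the metadata columns, so the
#' first occurrence of each identity is kept.
#'
#' @param gr A `GRanges`.
#' @return The sorted, deduplicated `GRanges`.
#' @export
sort_dedup <- function(gr) {
  if (length(gr) == 0L) return(gr)
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr),
             as.character(GenomicRanges::strand(gr)))
  gr <- gr[o]
  gr[!duplicated(gr)]
}

#' Feature identity strings
#'
#' Stable textual identity `contig:start-end(strand)` for each feature,
#' used to key match outcomes and provenance maps.
#'
#' @param gr A `GRanges`.
#' @return Character vector, one id per feature.
#' @export
feature_id <- function(gr) {
  if (length(gr) == 0L) return(character(0))
  sprintf("%s:%d-%d(%s)", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr), GenomicRanges::end(gr),
          as.character(GenomicRanges::strand(gr)))
}

# put two GRanges on a shared seqlevel universe so they can be compared
harmonize_seqlevels <- function(a, b) {
  lev <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lev
  GenomeInfoDb::seqlevels(b) <- lev
  list(a = a, b = b)
}

#' Pairwise overlap length between two features
#'
#' Number of genomic positions shared by `a` and `b` (1-based inclusive
#' arithmetic): `max(0, min(end) - max(start) + 1)` when the contigs agree,
#' 0 otherwise. Strand is ignored. Vectorized with recycling.
#'
#' @param a,b `GRanges` of equal (or recyclable) length.
#' @return Integer vector of shared nucleotide counts.
#' @examples
#' a <- cds_annotation("c1", 5, 50, "+")
#' b <- cds_annotation("c1", 20, 30, "-")
#' overlap_length(a, b)  # 11
#' @export
overlap_length <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(integer(0))
  ia <- rep_len(seq_along(a), n)
  ib <- rep_len(seq_along(b), n)
  same <- as.character(GenomicRanges::seqnames(a))[ia] ==
    as.character(GenomicRanges::seqnames(b))[ib]
  ol <- pmin(GenomicRanges::end(a)[ia], GenomicRanges::end(b)[ib]) -
    pmax(GenomicRanges::start(a)[ia], GenomicRanges::start(b)[ib]) + 1L
  as.integer(ifelse(same, pmax(0L, ol), 0L))
}

#' Is a CDS short?
#'
#' A CDS is "short" when its length is strictly below the threshold
#' (default 300 nt, roughly 100 codons).
#'
#' @param x A `GRanges` or a numeric vector of lengths in nt.
#' @param threshold Length bound in nt; lengths `< threshold` are short.
#' @return Logical vector.
#' @export
is_short <- function(x, threshold = 300) {
  len <- if (is.numeric(x)) x else GenomicRanges::width(x)
  len < threshold
}

#' Features overlapping another feature of the same annotation
#'
#' Returns the identities of all features sharing at least `min_overlap`
#' nucleotides with at least one *other* feature of the same annotation,
#' on either strand (same contig only).
#'
#' @param annotation A `GRanges`.
#' @param min_overlap Minimum shared nt (default 1).
#' @return Character vector of [feature_id()] values.
#' @export
overlapping_features <- function(annotation, min_overlap = 1L) {
  stopifnot(min_overlap >= 1L)
  if (length(annotation) < 2L) return(character(0))
  hits <- GenomicRanges::findOverlaps(annotation,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE, drop.self = TRUE)
  ids <- feature_id(annotation)
  unique(ids[sort(unique(S4Vectors::queryHits(hits)))])
}
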
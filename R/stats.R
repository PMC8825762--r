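# Genome / annotation composition statistics (per-genome overview table).

as_seq_character <- function(x) {
  if (is.character(x)) return(toupper(x))
  as.character(x)  # DNAString / DNAStringSet / BString
}

#' GC content of nucleotide sequences
#'
#' `100 * (G + C) / (A + C + G + T)`, reported to 2 decimals. `N` (and any
#' other ambiguity character) is excluded from both numerator and
#' denominator. An all-`N` (or empty) sequence has undefined GC content
#' and yields `NA` with a warning.
#'
#' @param x Character vector, `DNAString` or `DNAStringSet`.
#' @return Numeric vector of percents in `[0, 100]` (2 decimals), `NA`
#'   where undefined.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(x) {
  s <- as_seq_character(x)
  s <- gsub("[^ACGT]", "", s)
  out <- vapply(s, function(si) {
    n <- nchar(si)
    if (n == 0L) return(NA_real_)
    freq <- Biostrings::letterFrequency(Biostrings::DNAString(si), c("G", "C"))
    round(100 * sum(freq) / n, 2)
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(out)) warning("GC content undefined for all-N or empty sequence")
  out
}

contig_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

check_bounds <- function(annotation, genome) {
  if (length(annotation) == 0L) return(invisible(TRUE))
  lens <- contig_lengths(genome)
  ctg <- as.character(GenomicRanges::seqnames(annotation))
  missing_ctg <- setdiff(unique(ctg), names(lens))
  if (length(missing_ctg))
    stop("contig(s) absent from genome: ", paste(missing_ctg, collapse = ", "))
  bad <- which(GenomicRanges::end(annotation) > lens[ctg])
  if (length(bad))
    stop("feature extends past contig end: ", feature_id(annotation[bad[1]]))
  invisible(TRUE)
}

#' Fraction of the genome covered by CDS features
#'
#' `100 * |union of CDS intervals over all contigs| / total genome length`,
#' strand-ignored, overlapping intervals counted once, reported to
#' 2 decimals.
#'
#' @param annotation A CDS annotation (`GRanges`).
#' @param genome A `DNAStringSet` (contig lengths are taken from it).
#' @return Percent in `[0, 100]`.
#' @export
gene_density <- function(annotation, genome) {
  check_bounds(annotation, genome)
  total <- sum(contig_lengths(genome))
  if (length(annotation) == 0L) return(0)
  covered <- sum(GenomicRanges::width(
    GenomicRanges::reduce(GenomicRanges::granges(annotation),
                          ignore.strand = TRUE)))
  round(100 * covered / total, 2)
}

extract_codon <- function(genome_chars, contig, pos1, pos3, revcomp) {
  codon <- substr(genome_chars[[contig]], pos1, pos3)
  if (revcomp)
    codon <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", codon), "")[[1]]),
                   collapse = "")
  codon
}

codon_tally <- function(annotation, genome, which = c("start", "stop")) {
  which <- match.arg(which)
  if (length(annotation) == 0L) return(integer(0))
  if (any(GenomicRanges::width(annotation) < 3L)) {
    bad <- which(GenomicRanges::width(annotation) < 3L)[1]
    stop("feature shorter than 3 nt: ", feature_id(annotation[bad]))
  }
  check_bounds(annotation, genome)
  chars <- as.character(genome)
  ctg <- as.character(GenomicRanges::seqnames(annotation))
  st <- GenomicRanges::start(annotation)
  en <- GenomicRanges::end(annotation)
  minus <- as.character(GenomicRanges::strand(annotation)) == "-"
  # the biological 5' codon sits at the genomic start for forward genes and
  # at the genomic end (reverse-complemented) for reverse genes; vice versa
  # for the 3' codon
  use_end <- if (which == "start") minus else !minus
  p1 <- ifelse(use_end, en - 2L, st)
  codons <- vapply(seq_along(annotation), function(i)
    extract_codon(chars, ctg[i], p1[i], p1[i] + 2L, minus[i]), character(1))
  tab <- table(codons)
  stats::setNames(as.integer(tab), names(tab))
}

#' Tally of start codons in gene orientation
#'
#' The first codon of each CDS read 5' to 3' in gene orientation (for
#' reverse-strand genes, the reverse complement of the last 3 genomic nt).
#' Counts sum to the number of features.
#'
#' @inheritParams gene_density
#' @return Named integer vector, codon to count.
#' @export
start_codon_tally <- function(annotation, genome)
  codon_tally(annotation, genome, "start")

#' Tally of stop codons in gene orientation
#' @inheritParams gene_density
#' @return Named integer vector, codon to count.
#' @export
stop_codon_tally <- function(annotation, genome)
  codon_tally(annotation, genome, "stop")

#' Genome and annotation composition summary
#'
#' The per-genome overview: genome size, CDS count, gene density, GC
#' content, start/stop codon usage, longest CDS, and the number of short
#' CDSs (length below `short_threshold`).
#'
#' @inheritParams gene_density
#' @param genome Optional `DNAStringSet`; without it the sequence-derived
#'   fields (GC, density, codon tallies) are `NA`/empty.
#' @param short_threshold Short-CDS bound in nt (default 300, strict `<`).
#' @return A `genome_stats` list.
#' @export
genome_stats <- function(annotation, genome = NULL, short_threshold = 300) {
  has_genome <- !is.null(genome)
  n <- length(annotation)
  out <- list(
    genome_size = if (has_genome) sum(contig_lengths(genome)) else NA_integer_,
    cds_count = n,
    gene_density = if (has_genome) gene_density(annotation, genome) else NA_real_,
    gc_content = if (has_genome)
      gc_content(paste(as.character(genome), collapse = "")) else NA_real_,
    start_codon_tally = if (has_genome && n > 0)
      start_codon_tally(annotation, genome) else integer(0),
    stop_codon_tally = if (has_genome && n > 0)
      stop_codon_tally(annotation, genome) else integer(0),
    longest_cds = if (n > 0) max(GenomicRanges::width(annotation)) else 0L,
    short_cds_count = sum(is_short(annotation, short_threshold)),
    short_threshold = short_threshold
  )
  structure(out, class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat("Genome/annotation composition\n")
  cat(sprintf("  genome size      : %s nt\n",
              ifelse(is.na(x$genome_size), "NA", format(x$genome_size))))
  cat(sprintf("  CDS count        : %d\n", x$cds_count))
  cat(sprintf("  gene density     : %s%%\n",
              ifelse(is.na(x$gene_density), "NA", format(x$gene_density))))
  cat(sprintf("  GC content       : %s%%\n",
              ifelse(is.na(x$gc_content), "NA", format(x$gc_content))))
  cat(sprintf("  longest CDS      : %d nt\n", x$longest_cds))
  cat(sprintf("  short CDSs (<%d) : %d\n", x$short_threshold,
              x$short_cds_count))
  if (length(x$start_codon_tally)) {
    cat("  start codons     :",
        paste(sprintf("%s=%d", names(x$start_codon_tally),
                      x$start_codon_tally), collapse = " "), "\n")
  }
  invisible(x)
}
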
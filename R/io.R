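# GFF3 / FASTA I/O and the prediction-format registry.
#
# Parsing of well-formed GFF3 is delegated to rtracklayer; a lightweight
# validation pass first checks the records we are about to use so that
# malformed rows are reported with their line number, which rtracklayer
# does not do.

validate_gff3_lines <- function(lines, feature_types) {
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop(sprintf("GFF3 line %d: expected 9 tab-separated columns, found %d",
                   i, length(f)))
    if (!(f[3] %in% feature_types)) next
    if (!grepl("^[0-9]+$", f[4]) || !grepl("^[0-9]+$", f[5]))
      stop(sprintf("GFF3 line %d: non-integer coordinates '%s'/'%s'",
                   i, f[4], f[5]))
    if (as.numeric(f[4]) > as.numeric(f[5]))
      stop(sprintf("GFF3 line %d: start %s > end %s", i, f[4], f[5]))
    if (!(f[7] %in% c("+", "-")))
      stop(sprintf("GFF3 line %d: unknown strand symbol '%s'", i, f[7]))
  }
  invisible(length(body))
}

#' Read CDS features from a GFF3 file
#'
#' Retains exactly the records whose type column is in `feature_types`
#' (default `"CDS"`), with coordinates preserved verbatim (1-based
#' inclusive). Comment and directive lines are ignored. The result is
#' sorted and deduplicated by the identity tuple
#' (contig, start, end, strand).
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Character set of type-column values to keep.
#' @param contig_filter Optional character set; keep only these contigs.
#' @param source Optional label overriding the GFF source column (used to
#'   tag prediction sets with their tool name).
#' @return A CDS annotation (`GRanges`), see [cds_annotation()].
#' @export
read_gff3 <- function(path, feature_types = "CDS", contig_filter = NULL,
                      source = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(feature_types) == 0L) stop("feature_types must be non-empty")
  lines <- readLines(path, warn = FALSE)
  n_body <- validate_gff3_lines(lines, feature_types)
  if (n_body == 0L) {
    gr <- cds_annotation(character(0), integer(0), integer(0), character(0))
    return(gr)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (!is.null(contig_filter))
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% contig_filter]
  src <- if (!is.null(source)) source else {
    s <- as.character(gr$source)
    ifelse(is.na(s) | s == ".", "reference", s)
  }
  cds_annotation(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr), GenomicRanges::end(gr),
                 as.character(GenomicRanges::strand(gr)), source = src)
}

#' Write an annotation as GFF3
#'
#' Emits a `##gff-version 3` directive and one 9-column CDS row per
#' feature (1-based inclusive coordinates, phase 0). Reading the file
#' back with [read_gff3()] reproduces the identity-tuple set exactly,
#' and the output is byte-stable for a given input.
#'
#' @param annotation A CDS annotation (`GRanges`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  gr <- annotation
  mc <- S4Vectors::mcols(gr)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out)$source <- if ("source" %in% names(mc))
    as.character(mc$source) else rep("orfeval", length(gr))
  S4Vectors::mcols(out)$type <- rep("CDS", length(gr))
  S4Vectors::mcols(out)$phase <- rep(0L, length(gr))
  extra <- setdiff(names(mc), c("source", "type", "phase", "score"))
  for (nm in extra) S4Vectors::mcols(out)[[nm]] <- mc[[nm]]
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a genome FASTA file
#'
#' One entry per header (names truncated at the first whitespace).
#' Sequences are normalized: uppercased, `U` mapped to `T`, and any
#' character outside `{A,C,G,T}` mapped to `N`.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(first[1], ">"))
    stop("FASTA format error: sequence data before the first header in ", path)
  bs <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(bs))
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(bs))
  Biostrings::DNAStringSet(seqs)
}

# ---- prediction-format registry ------------------------------------------

.orfeval_formats <- new.env(parent = emptyenv())

#' Register a prediction input format
#'
#' The registry lets per-tool output dialects be added without touching
#' core code. A reader is a `function(path, source)` returning a CDS
#' annotation (`GRanges`). Formats `"gff3"` and `"tsv"` are built in;
#' the TSV dialect has columns `contig`, `start`, `stop`, `strand`
#' (tab-separated, with header).
#'
#' @param name Format name (case-insensitive).
#' @param reader A `function(path, source)` returning a `GRanges`.
#' @return `name`, invisibly.
#' @export
register_prediction_format <- function(name, reader) {
  stopifnot(is.character(name), is.function(reader))
  assign(tolower(name), reader, envir = .orfeval_formats)
  invisible(name)
}

#' List registered prediction formats
#' @return Character vector of format names.
#' @export
prediction_formats <- function() sort(ls(.orfeval_formats))

read_predictions_tsv <- function(path, source = "predictions") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "stop", "strand")
  if (!all(need %in% names(df)))
    stop("tabular prediction file must have columns: ",
         paste(need, collapse = ", "))
  # tolerate coordinates written 3'-to-5' on the reverse strand
  lo <- pmin(df$start, df$stop)
  hi <- pmax(df$start, df$stop)
  cds_annotation(df$contig, lo, hi, df$strand, source = source)
}

#' Read a prediction set in a registered format
#'
#' @param path Input file.
#' @param format A name from [prediction_formats()] (default `"gff3"`).
#' @param source Label for the producing tool.
#' @return A CDS annotation (`GRanges`).
#' @export
read_predictions <- function(path, format = "gff3", source = "predictions") {
  fmt <- tolower(format)
  if (!exists(fmt, envir = .orfeval_formats))
    stop("unknown prediction format '", format, "'; registered: ",
         paste(prediction_formats(), collapse = ", "))
  get(fmt, envir = .orfeval_formats)(path, source)
}

.onLoad <- function(libname, pkgname) {
  register_prediction_format("gff3", function(path, source)
    read_gff3(path, source = source))
  register_prediction_format("tsv", read_predictions_tsv)
}
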
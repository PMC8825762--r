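# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; nothing is read from disk except files
# the tests themselves write to tempdir().

suppressPackageStartupMessages({
  library(GenomicRanges)
})

ann <- function(start, end, strand = "+", contig = "c1", source = "test")
  cds_annotation(rep_len(contig, length(start)), start, end,
                 rep_len(strand, length(start)), source = source)

# n disjoint forward/reverse genes with codon-multiple lengths, spaced so
# that no two overlap
disjoint_genes <- function(n, len = 300, gap = 100, contig = "c1") {
  starts <- 1 + (0:(n - 1)) * (len + gap)
  ann(starts, starts + len - 1,
      strand = rep(c("+", "-"), length.out = n), contig = contig)
}

# a richer hand-built fixture containing an overlapping pair and a short
# gene, so that every primary metric is defined on self-comparison
rich_fixture <- function(contig = "c1") {
  cds_annotation(
    rep(contig, 5),
    start = c(101, 1001, 1301, 2001, 3001),
    end = c(400, 1330, 1600, 2150, 3900),
    strand = c("+", "+", "-", "+", "-"),
    source = "reference")
}

# Brute-force enumerate-and-sort oracle for single-gene classification:
# scores every prediction independently and picks by the stated ordering.
oracle_classify <- function(gene, predictions, threshold = 0.75) {
  gc_ <- as.character(seqnames(gene))
  gs_ <- as.character(strand(gene))
  g1 <- start(gene); g2 <- end(gene); glen <- width(gene)
  best <- NULL
  for (j in seq_along(predictions)) {
    p <- predictions[j]
    if (as.character(seqnames(p)) != gc_) next
    if (as.character(strand(p)) != gs_) next
    if ((start(p) - g1) %% 3 != 0) next
    ov <- min(end(p), g2) - max(start(p), g1) + 1
    if (ov < 0) ov <- 0
    if (ov / glen < threshold) next
    if (gs_ == "+") {
      sd_ <- g1 - start(p); ed_ <- end(p) - g2
    } else {
      sd_ <- end(p) - g2; ed_ <- g1 - start(p)
    }
    key <- c(abs(sd_) + abs(ed_), abs(sd_), start(p), width(p), j)
    if (is.null(best) || lex_less(key, best$key))
      best <- list(key = key, j = j, sd = sd_, ed = ed_, cov = ov / glen)
  }
  best
}

lex_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

# random small comparison instance: a gene plus a mix of shifted copies
# (in and out of frame) and unrelated intervals
random_instance <- function() {
  g1 <- sample(500:2000, 1)
  glen <- 3 * sample(30:150, 1)
  strand_g <- sample(c("+", "-"), 1)
  gene <- ann(g1, g1 + glen - 1, strand = strand_g)
  n_derived <- sample(0:6, 1)
  n_noise <- sample(0:6, 1)
  ps <- integer(0); pe <- integer(0); pstr <- character(0)
  for (k in seq_len(n_derived)) {
    s_off <- sample(-30:30, 1)   # nt, any frame
    e_off <- sample(-30:30, 1)
    s <- g1 + s_off
    e <- g1 + glen - 1 + e_off
    if (s < 1 || e <= s) next
    ps <- c(ps, s); pe <- c(pe, e)
    pstr <- c(pstr, sample(c(strand_g, "+", "-"), 1))
  }
  for (k in seq_len(n_noise)) {
    s <- sample(1:3000, 1)
    l <- sample(30:600, 1)
    ps <- c(ps, s); pe <- c(pe, s + l - 1)
    pstr <- c(pstr, sample(c("+", "-"), 1))
  }
  if (length(ps) == 0) {
    preds <- cds_annotation(character(0), integer(0), integer(0), character(0))
  } else {
    preds <- GRanges("c1", IRanges(ps, pe), strand = pstr)
    mcols(preds)$source <- "rand"
  }
  list(gene = gene, predictions = preds)
}

# planted-count fixture from the metric definitions: 100 genes, 80 exact
# prediction copies, 20 genes omitted, 10 spurious predictions that
# detect nothing
planted_80_20_10 <- function() {
  genes <- disjoint_genes(100, len = 300, gap = 120)
  copies <- genes[1:80]
  spur_start <- 100 * (300 + 120) + 5000 + (0:9) * 500
  spurious <- ann(spur_start, spur_start + 299, strand = "+")
  preds <- sort_dedup(suppressWarnings(c(
    {
      g <- copies; S4Vectors::mcols(g) <- NULL
      S4Vectors::mcols(g)$source <- rep("tool", length(g)); g
    },
    {
      s <- spurious; S4Vectors::mcols(s) <- NULL
      S4Vectors::mcols(s)$source <- rep("tool", length(s)); s
    })))
  list(reference = genes, predictions = preds)
}
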
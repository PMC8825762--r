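test_that("GFF3 reading filters, deduplicates and preserves coordinates", {
  gff <- tempfile(fileext = ".gff3")

  writeLines("##gff-version 3", gff)
  expect_length(read_gff3(gff), 0)

  writeLines(c(
    "##gff-version 3",
    "c1\ttoolX\tCDS\t10\t309\t.\t+\t0\tID=a",
    "c1\ttoolX\tCDS\t400\t702\t.\t-\t0\tID=b",
    "c1\ttoolX\tCDS\t400\t702\t.\t-\t0\tID=b_dup"), gff)
  a <- read_gff3(gff)
  expect_length(a, 2)
  expect_equal(start(a), c(10L, 400L))
  expect_equal(as.character(strand(a)), c("+", "-"))

  mixed <- c("##gff-version 3",
             "c1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=g1",
             "c1\tsrc\tCDS\t10\t309\t.\t+\t0\tID=c1f",
             "c1\tsrc\ttRNA\t500\t580\t.\t+\t.\tID=t1",
             "c1\tsrc\tCDS\t700\t999\t.\t-\t0\tID=c2f")
  writeLines(mixed, gff)
  a <- read_gff3(gff, feature_types = "CDS")
  # line-count oracle over the fixture text
  expect_length(a, sum(grepl("\tCDS\t", mixed)))
})

test_that("malformed GFF3 records are reported with their line number", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tCDS\t500\t309\t.\t+\t0\tID=bad"), gff)
  expect_error(read_gff3(gff), "line 2.*start 500 > end 309")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tCDS\t10\t309\t.\t?\t0\tID=bad"), gff)
  expect_error(read_gff3(gff), "line 2.*strand")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tCDS\tten\t309\t.\t+\t0\tID=bad"), gff)
  expect_error(read_gff3(gff), "line 2.*non-integer")
})

test_that("GFF3 round-trip preserves the identity-tuple set and is byte-stable", {
  withr::with_seed(42, {
    n <- 1000
    s <- sample(1:500000, n)
    a <- cds_annotation(sample(c("c1", "c2"), n, TRUE), s,
                        s + 3 * sample(30:200, n, TRUE) - 1,
                        sample(c("+", "-"), n, TRUE), source = "toolZ")
  })
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_gff3(a, f1)
  back <- read_gff3(f1)
  expect_identical(feature_id(back), feature_id(a))
  write_gff3(a, f2)
  expect_identical(readLines(f1), readLines(f2))

  empty <- cds_annotation(character(0), integer(0), integer(0), character(0))
  write_gff3(empty, f1)
  expect_true(any(grepl("gff-version 3", readLines(f1))))
  expect_length(read_gff3(f1), 0)
})

test_that("FASTA reading normalizes case, RNA and ambiguity codes", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), fa)
  g <- read_fasta(fa)
  expect_equal(as.character(g[["c1"]]), "ACGT")
  expect_equal(unname(Biostrings::width(g)), 4L)

  writeLines(c(">c1 description here", "ACGTAC", ">c2", "GG", "CC"), fa)
  g <- read_fasta(fa)
  expect_equal(names(g), c("c1", "c2"))
  expect_equal(unname(Biostrings::width(g)), c(6L, 4L))

  raw <- "acgTRYKMswUun"
  writeLines(c(">c1", raw), fa)
  g <- read_fasta(fa)
  # per-character oracle for the normalization map
  map1 <- function(ch) {
    ch <- toupper(ch)
    if (ch == "U") "T" else if (ch %in% c("A", "C", "G", "T")) ch else "N"
  }
  expected <- paste(vapply(strsplit(raw, "")[[1]], map1, character(1)),
                    collapse = "")
  expect_equal(as.character(g[[1]]), expected)

  writeLines(c("ACGT", ">c1", "ACGT"), fa)
  expect_error(read_fasta(fa), "before the first header")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "empty")
})

test_that("GC content excludes ambiguity codes from both terms", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("GCNNNN"), 100)  # N excluded entirely
  expect_equal(gc_content("ATGCNN"), 50)
  expect_warning(v <- gc_content("NNNN"), "undefined")
  expect_true(is.na(v))
})

test_that("gene density is the strand-ignored union coverage", {
  genome <- Biostrings::DNAStringSet(c(c1 = strrep("A", 30)))
  expect_equal(gene_density(ann(integer(0), integer(0)), genome), 0)
  a <- ann(c(1, 6), c(10, 15), strand = c("+", "-"))
  expect_equal(gene_density(a, genome), 50)  # union [1,15] = 15/30
  # duplication and reordering cannot change the union
  dup <- cds_annotation(c("c1", "c1", "c1"), c(6, 1, 1), c(15, 10, 10),
                        c("-", "+", "+"))
  expect_equal(gene_density(dup, genome), 50)
  off <- ann(20, 40)
  expect_error(gene_density(off, genome), "past contig end")
})

test_that("start codon tally honours strand and sums to the feature count", {
  genome <- Biostrings::DNAStringSet(c(c1 = "ATGAAACCCTAACATGGGTTTCAT"))
  #                                       123456789012345678901234
  # forward gene 1-12 starts ATG; reverse gene 13-24 ends ...CAT whose
  # reverse complement is ATG
  a <- cds_annotation(c("c1", "c1"), c(1, 13), c(12, 24), c("+", "-"))
  tal <- start_codon_tally(a, genome)
  expect_equal(tal[["ATG"]], 2L)
  expect_equal(sum(tal), length(a))

  tiny <- ann(1, 2)
  expect_error(start_codon_tally(tiny, genome), "shorter than 3")
})

test_that("a planted codon ledger is recovered exactly by the tallies", {
  # 100 genes, 30 nt each, with start codons fixed 70/20/10 ATG/GTG/TTG,
  # half on the reverse strand; the builder writes the sequence by hand
  codons <- rep(c("ATG", "GTG", "TTG"), times = c(70, 20, 10))
  n <- length(codons)
  gene_len <- 30L; gap <- 10L
  revcomp1 <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                             "")[[1]]), collapse = "")
  starts <- 1L + (seq_len(n) - 1L) * (gene_len + gap)
  strands <- rep(c("+", "-"), length.out = n)
  seq_chunks <- character(0)
  for (i in seq_len(n)) {
    body <- strrep("GCA", 8)
    gene <- paste0(codons[i], body, "TAA")
    if (strands[i] == "-") gene <- revcomp1(gene)
    seq_chunks <- c(seq_chunks, gene, strrep("A", gap))
  }
  genome <- Biostrings::DNAStringSet(c(c1 = paste(seq_chunks, collapse = "")))
  a <- cds_annotation(rep("c1", n), starts, starts + gene_len - 1L, strands)
  tal <- start_codon_tally(a, genome)
  expect_equal(tal[c("ATG", "GTG", "TTG")],
               c(ATG = 70L, GTG = 20L, TTG = 10L))
  expect_equal(sum(tal), n)
  stops <- stop_codon_tally(a, genome)
  expect_equal(stops[["TAA"]], n)
})

test_that("short-ORF boundary is strict at 300 nt", {
  expect_true(is_short(297))
  expect_false(is_short(300))
  expect_false(is_short(301))
  expect_true(is_short(ann(1, 297)))
  expect_false(is_short(ann(1, 300)))
})

test_that("overlap length matches shared-position enumeration", {
  expect_equal(overlap_length(ann(1, 10), ann(11, 20)), 0L)
  expect_equal(overlap_length(ann(1, 10), ann(10, 20)), 1L)
  count_shared <- function(a1, a2, b1, b2) length(intersect(a1:a2, b1:b2))
  expect_equal(overlap_length(ann(5, 50), ann(20, 30)),
               count_shared(5, 50, 20, 30))
  # different contigs never overlap
  expect_equal(overlap_length(ann(1, 10), ann(1, 10, contig = "c2")), 0L)
  withr::with_seed(9, {
    for (k in 1:50) {
      a1 <- sample(1:100, 1); a2 <- a1 + sample(0:50, 1)
      b1 <- sample(1:100, 1); b2 <- b1 + sample(0:50, 1)
      A <- ann(a1, a2); B <- ann(b1, b2)
      ol <- overlap_length(A, B)
      expect_identical(ol, overlap_length(B, A))        # symmetry
      expect_lte(ol, min(width(A), width(B)))           # bound
      expect_identical(as.integer(ol), as.integer(count_shared(a1, a2, b1, b2)))
    }
  })
})

test_that("overlapping_features applies the min-overlap gate pairwise", {
  expect_length(overlapping_features(disjoint_genes(5)), 0)
  touch <- ann(c(1, 10), c(10, 20), strand = c("+", "-"))
  expect_setequal(overlapping_features(touch, 1), feature_id(touch))
  # chain: A and B share 5 nt, B and C are disjoint
  chain <- ann(c(1, 96, 300), c(100, 200, 400))
  got <- overlapping_features(chain, min_overlap = 3)
  expect_setequal(got, feature_id(chain)[1:2])
})

test_that("genome_stats composes the constituent statistics", {
  empty <- cds_annotation(character(0), integer(0), integer(0), character(0))
  st <- genome_stats(empty)
  expect_equal(st$cds_count, 0)
  expect_equal(st$short_cds_count, 0)
  expect_equal(st$longest_cds, 0)

  g <- generate_genome(50000, 50, seed = 5)
  pl <- plant_annotation(g, 30, frac_short = 0.2, frac_overlapping = 0,
                         start_codon_profile = c(ATG = 1), seed = 6)
  st <- genome_stats(pl$annotation, pl$genome)
  expect_equal(st$cds_count, 30)
  expect_equal(st$short_cds_count, 6)       # exact by construction
  expect_equal(sum(st$start_codon_tally), 30)
  expect_equal(st$start_codon_tally[["ATG"]], 30L)
  expect_equal(st$longest_cds, max(width(pl$annotation)))
  expect_equal(st$gene_density,
               gene_density(pl$annotation, pl$genome))
})
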
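test_that("percentage difference reproduces the worked values", {
  expect_equal(percentage_difference(5, 5), 0)
  expect_equal(round(percentage_difference(2073, 1251), 2), 65.71)
  expect_equal(round(percentage_difference(71, 2478), 2), -97.13)
  expect_warning(v <- percentage_difference(3, 0), "zero reference")
  expect_true(is.na(v))
})

expect_identity_bundle <- function(b) {
  b <- unclass(b)
  for (nm in c("m1", "m2", "m5", "m10", "m11"))
    expect_equal(b[[nm]], 100, tolerance = 1e-12)
  for (nm in c("m3", "m4", "m6", "m7", "m8", "m9", "m12"))
    expect_equal(b[[nm]], 0, tolerance = 1e-12)
}

test_that("reference-vs-reference yields the identity bundle", {
  ref <- rich_fixture()
  rep <- match_annotations(ref, ref)
  expect_identity_bundle(compute_primary(rep, ref, ref))
})

test_that("planted 80/20/10 fixture gives the counted metric values", {
  fx <- planted_80_20_10()
  rep <- match_annotations(fx$reference, fx$predictions)
  b <- unclass(compute_primary(rep, fx$reference, fx$predictions))
  expect_equal(b[["m1"]], 80)
  expect_equal(round(b[["m2"]], 2), 88.89)   # 80 detectors / 90 predictions
  expect_equal(b[["m5"]], 100)
  expect_equal(round(b[["m10"]], 2), 88.89)
  expect_equal(b[["m11"]], 80)
  expect_equal(round(b[["m12"]], 2), 11.11)
  expect_equal(b[["m3"]], percentage_difference(90, 100))
})

test_that("uniform +6 nt start shifts give M6 = 2 codons and M7 = 0", {
  starts <- 101 + (0:19) * 500
  genes <- cds_annotation(rep("c1", 20), starts, starts + 299,
                          rep(c("+", "-"), 10))
  # elongate every prediction by 2 codons at the 5' end, in gene orientation
  fwd <- as.character(strand(genes)) == "+"
  ps <- start(genes) - ifelse(fwd, 6L, 0L)
  pe <- end(genes) + ifelse(fwd, 0L, 6L)
  preds <- cds_annotation(as.character(seqnames(genes)), ps, pe,
                          as.character(strand(genes)), source = "tool")
  rep <- match_annotations(genes, preds)
  expect_true(all(rep$gene_outcomes$start_diff_nt == 6L))
  b <- unclass(compute_primary(rep, genes, preds))
  expect_equal(b[["m6"]], 2)
  expect_equal(b[["m7"]], 0)
  expect_equal(b[["m5"]], 0)  # no perfect matches among detected
})

test_that("precision and FDR are complementary and degrade monotonically", {
  fx <- planted_80_20_10()
  spur2_start <- 200000 + (0:19) * 400
  more <- sort_dedup(suppressWarnings(c(
    fx$predictions,
    ann(spur2_start, spur2_start + 299, source = "tool"))))
  b1 <- unclass(compute_primary(match_annotations(fx$reference, fx$predictions),
                                fx$reference, fx$predictions))
  b2 <- unclass(compute_primary(match_annotations(fx$reference, more),
                                fx$reference, more))
  expect_equal(b1[["m10"]] + b1[["m12"]], 100, tolerance = 1e-12)
  expect_equal(b2[["m10"]] + b2[["m12"]], 100, tolerance = 1e-12)
  expect_lte(b2[["m10"]], b1[["m10"]])   # spurious additions never help
  expect_gte(b2[["m12"]], b1[["m12"]])
  # recall equals detection percentage under one-to-one assignment
  expect_equal(b1[["m1"]], b1[["m11"]])
  expect_equal(b2[["m1"]], b2[["m11"]])
})

test_that("M5 is 100 exactly when every detected gene is perfect", {
  fx <- planted_80_20_10()
  rep <- match_annotations(fx$reference, fx$predictions)
  b <- unclass(compute_primary(rep, fx$reference, fx$predictions))
  expect_equal(b[["m5"]], 100)
  # shift one prediction: M5 must drop below 100
  preds <- fx$predictions
  start(preds)[1] <- start(preds)[1] + 3L
  rep2 <- match_annotations(fx$reference, preds)
  b2 <- unclass(compute_primary(rep2, fx$reference, preds))
  expect_lt(b2[["m5"]], 100)
  # all-genes denominator variant
  b3 <- unclass(compute_primary(rep, fx$reference, fx$predictions,
                                m5_all_genes = TRUE))
  expect_equal(b3[["m5"]], 80)
})

test_that("undefined metrics propagate as NA, not zero", {
  ref <- disjoint_genes(5)
  empty <- cds_annotation(character(0), integer(0), integer(0), character(0))
  rep <- match_annotations(ref, empty)
  b <- unclass(compute_primary(rep, ref, empty))
  expect_true(all(is.na(b[c("m2", "m4", "m5", "m10", "m12")])))
  expect_equal(b[["m1"]], 0)
  expect_equal(b[["m3"]], -100)
})

test_that("secondary metrics partition genes by category", {
  # 5 overlapping pairs all detected perfectly, plus disjoint genes
  pair_starts <- 1 + (0:4) * 2000
  a <- cds_annotation(rep("c1", 10),
                      start = c(rbind(pair_starts, pair_starts + 270)),
                      end = c(rbind(pair_starts + 299, pair_starts + 569)),
                      strand = rep(c("+", "-"), 5))
  singles <- ann(20000 + (0:4) * 1000, 20000 + (0:4) * 1000 + 299)
  ref <- sort_dedup(suppressWarnings(c(a, singles)))
  rep <- match_annotations(ref, ref)
  sec <- compute_secondary(rep, ref, ref)
  expect_equal(sec$matched_overlapping_count, 10)
  expect_equal(sec$overlapping_ref_count, 10)
  b <- unclass(compute_primary(rep, ref, ref))
  expect_equal(b[["m8"]], 0)
  expect_equal(sec$length_by_category$detected, 300)
  expect_true(is.na(sec$length_by_category$MISSED))
})

test_that("missed genes planted in AT-rich sequence have lower GC", {
  rich <- strrep("GGCCAT", 50)   # 300 nt, GC ~ 66%
  poor <- strrep("ATATAT", 50)   # 300 nt, GC 0%
  spacer <- strrep("ACGT", 25)
  chunks <- c(rbind(rep(c(rich, poor), each = 5), spacer))
  genome <- Biostrings::DNAStringSet(c(c1 = paste(chunks, collapse = "")))
  starts <- 1 + (0:9) * 400
  ref <- ann(starts, starts + 299)
  preds <- ann(starts[1:5], starts[1:5] + 299)  # detect only the GC-rich half
  rep <- match_annotations(ref, preds)
  sec <- compute_secondary(rep, ref, preds, genome = genome)
  expect_lt(sec$gc_by_category$MISSED, sec$gc_by_category$detected)
  expect_equal(sum(sec$start_codon_usage_reference), 10)
})

test_that("genes encompassed by a foreign prediction are counted", {
  genes <- ann(c(100, 400), c(399, 699))
  pred <- ann(100, 699)
  rep <- match_annotations(genes, pred)
  sec <- compute_secondary(rep, genes, pred)
  # the losing gene is wholly inside a prediction it is not credited to
  expect_equal(sec$count_genes_encompassed, 1)
})

test_that("rank totalling matches a sort-based oracle and is order-invariant", {
  b1 <- c(m1 = 90, m2 = 80, m3 = 5, m4 = -2, m5 = 70, m6 = 1, m7 = 0,
          m8 = -10, m9 = 4, m10 = 80, m11 = 90, m12 = 20)
  b2 <- c(m1 = 95, m2 = 70, m3 = -8, m4 = 1, m5 = 60, m6 = 2, m7 = 1,
          m8 = 3, m9 = -20, m10 = 70, m11 = 95, m12 = 30)
  b3 <- c(m1 = 90, m2 = 60, m3 = 20, m4 = 0, m5 = 80, m6 = 0, m7 = 0,
          m8 = NA, m9 = 2, m10 = 60, m11 = 90, m12 = 40)
  long <- do.call(rbind, lapply(list(A = b1, B = b2, C = b3), function(b)
    data.frame(metric = names(b), value = as.numeric(b))))
  long$tool <- rep(c("A", "B", "C"), each = 12)
  long$genome <- "g1"
  rt <- rank_tools(long)

  # independent sort-based oracle
  orient <- metric_orientation()
  oracle_total <- sapply(c("A", "B", "C"), function(tl) {
    s <- 0
    for (mm in names(orient)) {
      vals <- sapply(c("A", "B", "C"), function(t2)
        long$value[long$tool == t2 & long$metric == mm])
      key <- switch(orient[[mm]], higher = -vals, zero = abs(vals),
                    lower = vals)
      key[is.na(key)] <- Inf
      r <- (rank(key, ties.method = "min") +
              rank(key, ties.method = "max")) / 2
      s <- s + r[[tl]]
    }
    s
  })
  got <- setNames(rt$total$total_rank, rt$total$tool)
  expect_equal(got[names(oracle_total)], oracle_total)

  # permutation invariance of the input rows
  withr::with_seed(3, {
    rt2 <- rank_tools(long[sample(nrow(long)), ])
  })
  expect_equal(rt2$total, rt$total)

  # single tool: summed rank is 12 per genome
  rt1 <- rank_tools(long[long$tool == "A", ])
  expect_equal(rt1$total$total_rank, 12)

  # a dominating tool ranks first on every metric
  dom <- c(m1 = 100, m2 = 100, m3 = 0, m4 = 0, m5 = 100, m6 = 0, m7 = 0,
           m8 = 0, m9 = 0, m10 = 100, m11 = 100, m12 = 0)
  wk <- c(m1 = 50, m2 = 50, m3 = 10, m4 = 5, m5 = 50, m6 = 3, m7 = 2,
          m8 = -5, m9 = 8, m10 = 50, m11 = 50, m12 = 50)
  long2 <- data.frame(
    tool = rep(c("dom", "weak"), each = 12), genome = "g1",
    metric = rep(names(dom), 2), value = c(dom, wk))
  rtd <- rank_tools(long2)
  expect_equal(rtd$total$tool, c("dom", "weak"))
  expect_true(all(rtd$ranks$rank[rtd$ranks$tool == "weak"] == 2))
})

test_that("nested bundle lists are accepted and missing genomes rank worst", {
  ref <- rich_fixture()
  rep <- match_annotations(ref, ref)
  perfect <- compute_primary(rep, ref, ref)
  nested <- list(good = list(g1 = perfect, g2 = perfect),
                 patchy = list(g1 = perfect))
  rt <- rank_tools(nested)
  expect_equal(rt$total$tool[1], "good")
  # on g2 the patchy tool has NA everywhere, hence rank 2 on all 12 metrics
  g2 <- rt$ranks[rt$ranks$genome == "g2" & rt$ranks$tool == "patchy", ]
  expect_true(all(g2$rank == 2))
})
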
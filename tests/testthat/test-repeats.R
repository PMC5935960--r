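mk_te <- function(chrom, start, end, family) {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), name = family, score = 0L,
                         strand = "+", family = family)
}

test_that("TE overlap applies the 10 nt floor against exonic bases", {
  tx <- mk_tx("t", "chr1", "+", list(c(0, 1000)))
  expect_equal(nrow(te_overlaps(tx, mk_te("chr1", 990, 1005, "LTR/Gypsy"))), 1L)
  expect_equal(nrow(te_overlaps(tx, mk_te("chr1", 991, 1000, "LTR/Gypsy"))), 0L)
  ## split overlap across two exons of one transcript accumulates per TE
  tx2 <- mk_tx("t2", "chr1", "+", list(c(0, 6), c(10, 16)))
  te <- mk_te("chr1", 0, 16, "LTR/Copia")
  res <- te_overlaps(tx2, te, min_overlap_bp = 10)
  expect_equal(res$overlap_bp, 12L)
  ## span mode counts the intron too
  res_span <- te_overlaps(tx2, te, min_overlap_bp = 10, mode = "span")
  expect_equal(res_span$overlap_bp, 16L)
})

test_that("te_overlaps agrees with the brute-force scan and ignores TE order", {
  set.seed(7)
  txs <- do.call(mk_txs, lapply(1:60, function(i)
    random_tx(sprintf("t%03d", i), max_pos = 3000, chroms = c("chr1", "chr2"))))
  tes <- data.table::rbindlist(lapply(1:40, function(i) {
    s <- sample.int(2900, 1)
    mk_te(sample(c("chr1", "chr2"), 1), s, s + sample.int(150, 1),
          sample(c("LTR/Gypsy", "LTR/Copia", "Simple_repeat"), 1))
  }))
  got <- te_overlaps(txs, tes)
  want <- oracle_te_overlap(as.data.frame(txs), as.data.frame(tes))
  key <- function(d) sort(paste(d$transcript_id, d$family, d$overlap_bp))
  expect_equal(key(got), key(want))
  shuf <- tes[sample(nrow(tes))]
  expect_equal(key(te_overlaps(txs, shuf)), key(got))
})

test_that("family enrichment matches hypergeometric enumeration", {
  ov <- data.table::data.table(
    transcript_id = c(paste0("a", 1:10), paste0("b", 1:20)),
    family = "LTR/Gypsy", overlap_bp = 50L)
  A <- paste0("a", 1:100); B <- paste0("b", 1:100)
  res <- family_enrichment(A, B, ov, "LTR/Gypsy")
  expect_equal(unname(res$table[1, ]), c(10L, 90L))
  expect_equal(unname(res$table[2, ]), c(20L, 80L))
  expect_equal(res$p_value, oracle_fisher_p(10, 90, 20, 80), tolerance = 1e-9)
  expect_equal(res$odds_ratio, (10 * 80) / (90 * 20))
  ## identical proportions: odds ratio 1, p = 1
  res_eq <- family_enrichment(paste0("a", 1:100), paste0("c", 1:100),
                              rbind(ov, data.table::data.table(
                                transcript_id = paste0("c", 1:10),
                                family = "LTR/Gypsy", overlap_bp = 50L)),
                              "LTR/Gypsy")
  expect_equal(res_eq$odds_ratio, 1)
  expect_equal(res_eq$p_value, 1)
  ## extreme 5-vs-5 table agrees with the enumeration oracle
  ov5 <- data.table::data.table(transcript_id = paste0("x", 1:5),
                                family = "F", overlap_bp = 10L)
  res5 <- family_enrichment(paste0("x", 1:5), paste0("y", 1:5), ov5, "F")
  expect_equal(res5$p_value, oracle_fisher_p(5, 0, 0, 5), tolerance = 1e-9)
  expect_error(family_enrichment(character(0), B, ov, "F"), "empty")
  expect_error(family_enrichment(c("a1", "s"), c("a1"), ov, "F"), "disjoint")
})

test_that("window density tiles, counts by start, and conserves totals", {
  feats <- data.table::data.table(chrom = "chr1",
                                  start = c(10L, 600000L, 1100000L),
                                  end = c(100L, 600100L, 1100100L))
  d <- window_density(feats, c(chr1 = 1200000L), window_bp = 500000L)
  expect_equal(nrow(d), 3L)                       # last partial window included
  expect_equal(d$count, c(1L, 1L, 1L))
  expect_equal(d$window_end[3], 1200000L)
  ## empty chromosome still emits zero rows
  d2 <- window_density(feats[0], c(chr1 = 1200000L), window_bp = 500000L)
  expect_equal(d2$count, c(0L, 0L, 0L))
  ## boundary straddler counts once, in the window holding its start
  d3 <- window_density(data.table::data.table(chrom = "chr1", start = 499999L,
                                              end = 500050L),
                       c(chr1 = 1200000L), window_bp = 500000L)
  expect_equal(d3$count, c(1L, 0L, 0L))
  ## conservation under random placements
  set.seed(9)
  feats4 <- data.table::data.table(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                                   start = sample.int(999999L, 200))
  d4 <- window_density(feats4, c(chr1 = 1000000L, chr2 = 1000000L), 250000L)
  agg <- tapply(d4$count, d4$chrom, sum)
  expect_equal(as.vector(agg), as.vector(table(feats4$chrom)))
})
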
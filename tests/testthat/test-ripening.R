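## a minimal 2/3-stage design: `reps` replicates per stage
mk_stage_design <- function(stages, reps) {
  data.table::data.table(
    sample_id = paste0(rep(gsub("\\+", "p", stages), each = reps), "_r",
                       seq_len(reps)),
    tissue = NA_character_,
    stage = rep(stages, each = reps),
    replicate = rep(seq_len(reps), length(stages)))
}

test_that("expressed_set uses a strict mean-FPKM floor", {
  d <- mk_stage_design(c("MG", "BR"), 2)
  mat <- rbind(keep = c(12, 9, 0, 0), edge = c(10, 10, 0, 0), lo = c(1, 1, 50, 50))
  colnames(mat) <- d$sample_id
  expect_equal(expressed_set(mat, d, "MG"), "keep")   # mean 10.5 > 10
  expect_equal(expressed_set(mat, d, "BR"), "lo")
  expect_error(expressed_set(mat, d, "BR+7"), "not present")
})

test_that("de_test fold changes, degenerate cases and BH behave as stated", {
  d <- mk_stage_design(c("MG", "BR"), 2)
  mat <- rbind(de = c(40, 40, 10, 10), flat = c(7, 7, 7, 7))
  colnames(mat) <- d$sample_id
  res <- de_test(mat, d, c("MG", "BR"))
  expect_equal(res[res$transcript_id == "de"]$log2fc, log2(41 / 11))
  ## identical replicate sets in both stages: log2fc 0, p 1 (both methods)
  expect_equal(res[res$transcript_id == "flat"]$log2fc, 0)
  expect_equal(res[res$transcript_id == "flat"]$p, 1)
  resp <- de_test(mat, d, c("MG", "BR"), method = "permutation")
  expect_equal(resp[resp$transcript_id == "flat"]$p, 1)
  ## exact permutation enumeration at 2+2 replicates: best possible p = 2/6
  expect_equal(resp[resp$transcript_id == "de"]$p, 1 / 3)
  ## external p-values pass straight through to BH
  ext <- c(de = 0.01, flat = 0.02)
  rese <- de_test(mat, d, c("MG", "BR"), external_p = ext)
  expect_equal(rese$p, c(0.01, 0.02))
  expect_equal(rese$q, oracle_bh(c(0.01, 0.02)))
})

test_that("BH q-values match the hand rule and its invariants", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- stats::p.adjust(p, "BH")
  expect_equal(q, c(0.04, 0.04, 0.04, 0.04))   # m = 4 hand computation
  expect_equal(q, oracle_bh(p))
  set.seed(21)
  for (i in 1:20) {
    p <- stats::runif(30)
    q <- stats::p.adjust(p, "BH")
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("venn_partition covers its regions and conserves the union", {
  v <- venn_partition(c("a", "b", "c"), c("b", "c", "d"), "c")
  expect_equal(unname(v), c(1L, 1L, 0L, 1L, 0L, 0L, 1L))
  expect_equal(sum(v), 4L)
  v2 <- venn_partition("x", "y", "z")
  expect_equal(unname(v2), c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
  v3 <- venn_partition(c("p", "q"), c("p", "q"), c("p", "q"))
  expect_equal(unname(v3["ABC"]), 2L)
  expect_equal(sum(v3), 2L)
})

test_that("nearest_mrna distances use half-open gap arithmetic with id tie-break", {
  q <- tx_spans(mk_tx("lnc", "chr1", "+", list(c(5000, 5800))))
  m <- tx_spans(mk_txs(mk_tx("mB", "chr1", "+", list(c(9000, 9500)), biotype = "coding"),
                       mk_tx("mA", "chr1", "-", list(c(1000, 2500)), biotype = "coding")))
  res <- nearest_mrna(q, m)
  expect_equal(res$mrna_id, "mA")
  expect_equal(res$distance_bp, 2500L)
  ## book-ended spans are at distance 0
  q0 <- tx_spans(mk_tx("l0", "chr1", "+", list(c(0, 100))))
  m0 <- tx_spans(mk_tx("m0", "chr1", "+", list(c(100, 200)), biotype = "coding"))
  expect_equal(nearest_mrna(q0, m0)$distance_bp, 0L)
  ## equidistant candidates resolve to the lexicographically smallest id
  qt <- tx_spans(mk_tx("lt", "chr1", "+", list(c(1000, 1100))))
  mt <- tx_spans(mk_txs(mk_tx("mZ", "chr1", "+", list(c(800, 900)), biotype = "coding"),
                        mk_tx("mY", "chr1", "+", list(c(1200, 1300)), biotype = "coding")))
  expect_equal(nearest_mrna(qt, mt)$mrna_id, "mY")
  ## no same-chromosome candidate: NA, logged
  q2 <- tx_spans(mk_tx("far", "chrX", "+", list(c(0, 100))))
  expect_message(res2 <- nearest_mrna(q2, m), "no same-chromosome")
  expect_true(is.na(res2$distance_bp))
})

test_that("nearest_mrna agrees with the all-pairs oracle", {
  set.seed(31)
  m <- tx_spans(do.call(mk_txs, lapply(1:40, function(i)
    random_tx(sprintf("m%03d", i), max_pos = 50000, chroms = c("chr1", "chr2")))))
  q <- tx_spans(do.call(mk_txs, lapply(1:100, function(i)
    random_tx(sprintf("q%03d", i), max_pos = 50000, chroms = c("chr1", "chr2")))))
  res <- nearest_mrna(q, m)
  for (i in seq_len(nrow(q))) {
    o <- oracle_nearest(q$start[i], q$end[i], q$chrom[i], m)
    expect_equal(res$distance_bp[i], o$d)
    expect_equal(res$mrna_id[i], o$id)
  }
})

test_that("pair correlations are exact for (anti)proportional profiles", {
  d <- mk_stage_design(c("MG", "BR", "BR+7"), 2)
  mrna <- 2^(1:6)
  mat <- rbind(lnc_pos = 2 * mrna, lnc_neg = 64 / mrna, mrna = mrna)
  colnames(mat) <- d$sample_id
  spans_l <- tx_spans(mk_txs(mk_tx("lnc_pos", "chr1", "+", list(c(1000, 1400))),
                             mk_tx("lnc_neg", "chr1", "-", list(c(8000, 8400)))))
  spans_m <- tx_spans(mk_tx("mrna", "chr1", "+", list(c(2000, 2600)), biotype = "coding"))
  pairs <- pair_and_correlate(c("lnc_pos", "lnc_neg"), "mrna", spans_l, spans_m,
                              mat, d, max_distance = 10000, pseudocount = 0)
  expect_equal(nrow(pairs), 2L)
  expect_equal(pairs[pairs$lnc_id == "lnc_pos"]$pearson_r, 1)
  expect_equal(pairs[pairs$lnc_id == "lnc_neg"]$pearson_r, -1)
  expect_equal(attr(pairs, "frac_within_30kb"), 1)
  ## textbook covariance formula agreement on a 10-sample fixture
  d10 <- mk_stage_design(c("MG", "BR"), 5)
  set.seed(41)
  x <- stats::runif(10, 1, 100); y <- stats::runif(10, 1, 100)
  mat10 <- rbind(l = x, m = y)
  colnames(mat10) <- d10$sample_id
  p10 <- pair_and_correlate("l", "m",
                            tx_spans(mk_tx("l", "chr1", "+", list(c(100, 300)))),
                            tx_spans(mk_tx("m", "chr1", "+", list(c(400, 700)), biotype = "coding")),
                            mat10, d10, max_distance = 10000, pseudocount = 1)
  lx <- log2(x + 1); ly <- log2(y + 1)
  r_hand <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(p10$pearson_r, r_hand)
  ## zero-variance profile: pair retained, r undefined
  matz <- rbind(l = rep(5, 10), m = y)
  colnames(matz) <- d10$sample_id
  pz <- pair_and_correlate("l", "m",
                           tx_spans(mk_tx("l", "chr1", "+", list(c(100, 300)))),
                           tx_spans(mk_tx("m", "chr1", "+", list(c(400, 700)), biotype = "coding")),
                           matz, d10, max_distance = 10000)
  expect_equal(nrow(pz), 1L)
  expect_true(is.na(pz$pearson_r))
})

test_that("pairing threshold is strict and 30 kb fraction is reported", {
  d <- mk_stage_design(c("MG", "BR"), 2)
  mat <- matrix(stats::runif(12, 1, 50), nrow = 3,
                dimnames = list(c("l1", "l2", "m1"), d$sample_id))
  spans_l <- tx_spans(mk_txs(mk_tx("l1", "chr1", "+", list(c(0, 100))),
                             mk_tx("l2", "chr1", "+", list(c(50000, 50100)))))
  spans_m <- tx_spans(mk_tx("m1", "chr1", "+", list(c(10100, 10200)), biotype = "coding"))
  pairs <- pair_and_correlate(c("l1", "l2"), "m1", spans_l, spans_m, mat, d,
                              max_distance = 10000)
  ## l1 gap is exactly 10000: strictly-within fails; l2 is 39800 away
  expect_equal(nrow(pairs), 0L)
  expect_equal(attr(pairs, "frac_within_30kb"), 0.5)
})
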
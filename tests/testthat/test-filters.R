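test_that("length filter is strict at the 200 bp boundary", {
  txs <- mk_txs(mk_tx("short", "chr1", "+", list(c(0, 199))),
                mk_tx("exact", "chr1", "+", list(c(0, 200))),
                mk_tx("split", "chr1", "+", list(c(0, 100), c(500, 599))))
  kept <- unique(filter_length(txs, 200)$transcript_id)
  expect_setequal(kept, "exact")          # 199 removed, 200 kept, 100+99 removed
  empty <- filter_length(txs[0], 200)
  expect_equal(nrow(empty), 0L)
})

hit_row <- function(id, db, e, ident, aln, cov) {
  data.table::data.table(query_id = id, database = db, e_value = e,
                         identity_pct = ident, alignment_length = aln,
                         query_coverage_pct = cov)
}

test_that("homology removal needs every criterion of one hit simultaneously", {
  ids <- c("t1", "t2", "t3", "t4")
  hits <- rbind(
    hit_row("t1", "EST", 1e-11, 85, 300, 85),      # all pass -> removed
    hit_row("t2", "EST", 1e-11, 80, 300, 85),      # identity not > 80 -> kept
    hit_row("t3", "protein", 1e-9, 90, 120, 50),   # e-value fails -> kept
    hit_row("t4", "ncRNA", 1e-12, 95, 22, 50))     # alignment not > 22 -> kept
  res <- filter_homology(ids, hits)
  expect_setequal(res$kept, c("t2", "t3", "t4"))
  expect_named(res$removed, "t1")
  ## boundary on the other side: alignment 23 removes
  res2 <- filter_homology("t4", hit_row("t4", "ncRNA", 1e-12, 95, 23, 50))
  expect_equal(res2$kept, character(0))
  ## hits for unknown transcripts warn and are ignored
  expect_warning(filter_homology("t1", hit_row("zz", "EST", 1e-11, 85, 300, 85)),
                 "unknown")
})

test_that("coding potential score implements the stated ORF formula", {
  ## 150-codon ORF (450 nt incl stop) in a 600 nt transcript:
  ## aa term 150/100 = 1.5, coverage term (450/600)/0.5 = 1.5 -> score 0.5
  s1 <- paste0("ATG", strrep("GCT", 148), "TAA", strrep("C", 150))
  expect_equal(coding_potential_score(s1), 0.5)
  ## 300 nt, longest ORF 60 nt (20 aa, coverage 0.2): max(0.2, 0.4) - 1 = -0.6
  s2 <- paste0("ATG", strrep("GCT", 18), "TAA", strrep("C", 240))
  expect_equal(coding_potential_score(s2), -0.6)
  ## no ATG at all: ORF length 0 -> score -1
  expect_equal(coding_potential_score(strrep("CGT", 100)), -1)
  expect_error(coding_potential_score(""), "empty")
})

test_that("expression filter keeps FPKM > 1 in at least one sample, strictly", {
  mat <- rbind(a = c(0.4, 1.2, 0.0), b = c(1.0, 1.0, 1.0), c = c(0, 0, 0))
  colnames(mat) <- paste0("s", 1:3)
  expect_equal(filter_expression(c("a", "b", "c"), mat), "a")
  ## absent transcripts are all-zero (logged), not an error
  expect_message(out <- filter_expression(c("a", "zz"), mat), "absent")
  expect_equal(out, "a")
})

test_that("the cascade is monotone, auditable, and identity under vacuous thresholds", {
  cfg <- sim_config(seed = 11, fpkm_dispersion = 0)
  g <- simulate_genome(cfg)
  expr <- simulate_expression(g$truth, cfg)
  hits <- lncfruit:::simulate_hits(g$truth)
  seqs <- lncfruit:::simulate_sequences(g$novel, g$truth, cfg)
  cls <- classify_transcripts(g$novel, g$reference)
  res <- run_cascade(cls, g$novel, hits, seqs, expr$mat)
  ## report bookkeeping: surviving = input - removed, chained stage to stage
  expect_equal(res$report$surviving, res$report$input - res$report$removed)
  expect_equal(res$report$input[-1], res$report$surviving[-nrow(res$report)])
  ## monotonicity: final set is a subset of the classified non-discarded set
  expect_true(all(res$lnc$transcript_id %in% cls[label != "discarded"]$transcript_id))
  ## vacuous thresholds pass everything through
  vac <- filter_thresholds(min_length_bp = 0,
                           est = list(max_e = -1, min_coverage_pct = 101, min_identity_pct = 101),
                           ncrna = list(max_e = -1, min_identity_pct = 101, min_alignment_bp = Inf),
                           protein = list(max_e = -1, min_alignment = Inf),
                           coding_score_cut = Inf, min_fpkm = -1)
  res_vac <- run_cascade(cls, g$novel, hits, seqs, expr$mat, vac)
  expect_setequal(res_vac$lnc$transcript_id, cls[label != "discarded"]$transcript_id)
})

test_that("cascade order is shuffle-invariant within a stage", {
  cfg <- sim_config(seed = 12, n_linc = 20, n_anc = 10, n_slnc = 5,
                    n_intronic = 5, n_decoy = 10, fpkm_dispersion = 0)
  g <- simulate_genome(cfg)
  expr <- simulate_expression(g$truth, cfg)
  hits <- lncfruit:::simulate_hits(g$truth)
  seqs <- lncfruit:::simulate_sequences(g$novel, g$truth, cfg)
  cls <- classify_transcripts(g$novel, g$reference)
  res1 <- run_cascade(cls, g$novel, hits, seqs, expr$mat)
  set.seed(1)
  cls_sh <- cls[sample(nrow(cls))]
  hits_sh <- hits[sample(nrow(hits))]
  res2 <- run_cascade(cls_sh, g$novel, hits_sh, seqs, expr$mat)
  expect_setequal(res1$lnc$transcript_id, res2$lnc$transcript_id)
  expect_equal(res1$report$surviving, res2$report$surviving)
})

test_that("category percentages round half-up to one decimal and sum to ~100", {
  expect_equal(category_percentages(c(70635, 8085, 602)), c(89.0, 10.2, 0.8))
  expect_equal(round_half_up(10.25, 1), 10.3)   # not banker's rounding
  set.seed(3)
  for (i in 1:20) {
    cts <- sample.int(1000, 4)
    expect_lte(abs(sum(category_percentages(cts)) - 100), 0.1 + 1e-9)
  }
})
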
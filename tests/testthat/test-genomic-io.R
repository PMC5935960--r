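test_that("GTF coordinates are converted to 0-based half-open and exons sorted", {
  f <- write_lines_tmp(c(
    'chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t2001\t2500\t.\t+\t.\tgene_id "g2"; transcript_id "t2";',
    'chr1\tsrc\texon\t1001\t1300\t.\t+\t.\tgene_id "g2"; transcript_id "t2";'),
    ".gtf")
  tx <- read_gtf(f)
  t1 <- tx[tx$transcript_id == "t1", ]
  expect_equal(t1$start, 1000L)
  expect_equal(t1$end, 1500L)
  t2 <- tx[tx$transcript_id == "t2", ]
  expect_equal(t2$start, c(1000L, 2000L))  # returned sorted despite file order
  expect_equal(t2$end, c(1300L, 2500L))
})

test_that("GTF round trip is record-equivalent and unstranded transcripts are flagged", {
  lines <- c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\tsrc\texon\t501\t700\t.\t-\t.\tgene_id "gB"; transcript_id "tB";',
    'chr2\tsrc\texon\t11\t90\t.\t+\t.\tgene_id "gC"; transcript_id "tC";',
    'chr2\tsrc\texon\t201\t260\t.\t.\t.\tgene_id "gD"; transcript_id "tD";',
    'chr2\tsrc\texon\t301\t360\t.\t-\t.\tgene_id "gE"; transcript_id "tE";')
  f <- write_lines_tmp(lines, ".gtf")
  tx <- read_gtf(f)
  expect_equal(unstranded_ids(tx), "tD")   # carried, not dropped
  f2 <- tempfile(fileext = ".gtf")
  write_gtf(tx, f2)
  tx2 <- read_gtf(f2)
  expect_equal(as.data.frame(tx2), as.data.frame(tx))
})

test_that("malformed GTF errors name the offending line", {
  f <- write_lines_tmp(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.'), ".gtf")
  expect_error(read_gtf(f), "line 2")
  f <- write_lines_tmp(
    'chr1\tsrc\texon\t500\t400\t.\t+\t.\tgene_id "g"; transcript_id "t";', ".gtf")
  expect_error(read_gtf(f), "line 1.*coordinates")
  f <- write_lines_tmp(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g";', ".gtf")
  expect_error(read_gtf(f), "transcript_id")
})

test_that("GFF3 reader keeps only protein-coding transcripts", {
  f <- write_lines_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t3000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1001\t3000\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tParent=m1",
    "chr1\tsrc\texon\t2001\t3000\t.\t+\t.\tParent=m1",
    "chr1\tsrc\tmRNA\t5001\t5600\t.\t-\t.\tID=m2;Parent=g2",
    "chr1\tsrc\texon\t5001\t5600\t.\t-\t.\tParent=m2",
    "chr1\tsrc\tmRNA\t7001\t7600\t.\t+\t.\tID=m3;Parent=g3",
    "chr1\tsrc\texon\t7001\t7600\t.\t+\t.\tParent=m3",
    "chr1\tsrc\tncRNA\t9001\t9600\t.\t+\t.\tID=n1",
    "chr1\tsrc\texon\t9001\t9600\t.\t+\t.\tParent=n1",
    "chr1\tsrc\ttRNA\t9901\t9990\t.\t+\t.\tID=n2",
    "chr1\tsrc\texon\t9901\t9990\t.\t+\t.\tParent=n2"), ".gff3")
  ref <- read_reference_gff3(f)
  expect_setequal(unique(ref$transcript_id), c("m1", "m2", "m3"))  # 3 of 5
  expect_true(all(ref$biotype == "coding"))
  m1 <- ref[ref$transcript_id == "m1", ]
  expect_equal(m1$start, c(1000L, 2000L))
  expect_equal(m1$end, c(1500L, 3000L))
  m2 <- ref[ref$transcript_id == "m2", ]
  expect_equal(m2$strand, "-")
})

test_that("orphan exons in GFF3 are an error", {
  f <- write_lines_tmp(c(
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tParent=m1",
    "chr1\tsrc\texon\t5001\t5200\t.\t+\t.\tParent=ghost"), ".gff3")
  expect_error(read_reference_gff3(f), "orphan exon.*line 3")
})

test_that("methylation reports convert to 0-based, keep zero coverage, reject bad context", {
  f <- write_lines_tmp(c(
    "chrom\tpos\tstrand\tmeth_count\tunmeth_count\tcontext",
    "chr1\t101\t+\t3\t1\tCG",
    "chr1\t50\t+\t0\t0\tCHH"), ".tsv")
  rec <- read_methylation_report(f)
  expect_equal(rec$pos, c(100L, 49L))
  expect_equal(rec$meth_count[2] + rec$unmeth_count[2], 0L)  # retained
  f <- write_lines_tmp(c(
    "chrom\tpos\tstrand\tmeth_count\tunmeth_count\tcontext",
    "chr1\t101\t+\t3\t1\tCHX"), ".tsv")
  expect_error(read_methylation_report(f), "CHX")
})

test_that("BED and GTF describing the same bases give identical internal intervals", {
  ## physical bases 1000..1499 on chr1: GTF writes 1001-1500, BED writes 1000,1500
  g <- write_lines_tmp(
    'chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tgene_id "g"; transcript_id "t";', ".gtf")
  b <- write_lines_tmp("chr1\t1000\t1500\tte1\t0\t+\tLTR/Gypsy", ".bed")
  tx <- read_gtf(g)
  te <- read_te_bed(b)
  expect_equal(c(tx$start, tx$end), c(te$start, te$end))
})

test_that("homology hit tables validate bounds and database names", {
  hdr <- "query_id\tdatabase\te_value\tidentity_pct\talignment_length\tquery_coverage_pct"
  f <- write_lines_tmp(c(hdr, "t1\tEST\t1e-12\t85\t300\t90"), ".tsv")
  h <- read_homology_hits(f)
  expect_equal(h$database, "EST")
  f <- write_lines_tmp(c(hdr, "t1\tSwissProt\t1e-12\t85\t300\t90"), ".tsv")
  expect_error(read_homology_hits(f), "database")
  f <- write_lines_tmp(c(hdr, "t1\tEST\t1e-12\t130\t300\t90"), ".tsv")
  expect_error(read_homology_hits(f), "\\[0, 100\\]")
})

test_that("transcript_set enforces its invariants", {
  expect_error(mk_tx("t", "chr1", "+", list(c(100, 100))), "start < end")
  expect_error(mk_tx("t", "chr1", "*", list(c(100, 200))), "strand")
  expect_error(mk_tx("t", "chr1", "+", list(c(100, 250), c(200, 300))),
               "overlapping")
  tx <- mk_tx("t", "chr1", "+", list(c(300, 400), c(100, 200)))
  expect_equal(tx$start, c(100L, 300L))  # sorted on construction
  expect_equal(tx_spans(tx)$start, 100L)
  expect_equal(tx_spans(tx)$end, 400L)
  expect_equal(unname(tx_lengths(tx)), 200L)
  expect_equal(tx_introns(tx)$start, 200L)
  expect_equal(tx_introns(tx)$end, 300L)
})
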
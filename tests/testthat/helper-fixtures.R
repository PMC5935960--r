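## In-code fixtures: tiny transcript sets and on-disk format snippets.

## exons: list of c(start, end) pairs, 0-based half-open
mk_tx <- function(id, chrom, strand, exons, biotype = "novel", gene_id = id) {
  ex <- do.call(rbind, exons)
  transcript_set(data.frame(
    transcript_id = id, gene_id = gene_id, chrom = chrom,
    start = ex[, 1], end = ex[, 2], strand = strand, biotype = biotype))
}

mk_txs <- function(...) {
  parts <- list(...)
  out <- data.table::rbindlist(parts)
  data.table::setattr(out, "class", class(parts[[1]]))
  out
}

## a 2-exon reference transcript: exons [1000,1500) and [2000,2500)
ref_two_exon <- function(strand = "+", id = "REF1") {
  mk_tx(id, "chr1", strand, list(c(1000, 1500), c(2000, 2500)), biotype = "coding")
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

## random single-exon-per-row transcript pair generator for oracle tests
random_tx <- function(id, max_pos = 5000, max_exons = 3, chroms = "chr1",
                      strands = c("+", "-")) {
  n_ex <- sample.int(max_exons, 1)
  bounds <- sort(sample.int(max_pos, 2 * n_ex))
  starts <- bounds[seq(1, 2 * n_ex, by = 2)]
  ends <- bounds[seq(2, 2 * n_ex, by = 2)]
  keep <- starts < ends
  if (!any(keep)) return(random_tx(id, max_pos, max_exons, chroms, strands))
  mk_tx(id, sample(chroms, 1), sample(strands, 1),
        Map(c, starts[keep], ends[keep]))
}
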
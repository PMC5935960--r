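## Transposable-element overlap calls, per-family Fisher enrichment, and
## fixed-width window density tables.

#' TE overlap calls
#'
#' A TE feature counts as overlapping a transcript iff the intersection of
#' the TE interval with the transcript's exonic bases (default) or its
#' genomic span (`mode = "span"`) totals at least `min_overlap_bp`
#' (default 10 nt), strand-ignorant.
#'
#' @param tx a [transcript_set]
#' @param tes TE table from [read_te_bed()]
#' @param min_overlap_bp minimum total intersection in bp
#' @param mode `"exon"` (overlap against exonic bases) or `"span"`
#' @return data.table of (transcript_id, family, overlap_bp), one row per
#'   transcript/TE-feature pair that passes, `overlap_bp` summed per pair
#' @export
te_overlaps <- function(tx, tes, min_overlap_bp = 10, mode = c("exon", "span")) {
  mode <- match.arg(mode)
  feats <- if (mode == "exon") {
    tx[, .(transcript_id, chrom, start, end)]
  } else {
    tx_spans(tx)[, .(transcript_id, chrom, start, end)]
  }
  te <- data.table::as.data.table(tes)[, .(chrom, start, end, family)]
  te[, te_idx := .I]
  data.table::setkey(te, chrom, start, end)
  hits <- data.table::foverlaps(feats, te, type = "any", nomatch = NULL)
  if (!nrow(hits))
    return(data.table::data.table(transcript_id = character(0),
                                  family = character(0), overlap_bp = integer(0)))
  hits[, ov := pmin(end, i.end) - pmax(start, i.start)]
  per_pair <- hits[, .(overlap_bp = sum(ov), family = family[1L]),
                   by = .(transcript_id, te_idx)]
  out <- per_pair[overlap_bp >= min_overlap_bp,
                  .(transcript_id, family, overlap_bp)]
  data.table::setorder(out, transcript_id, family)
  out[]
}

#' Per-family overlap enrichment between two transcript groups
#'
#' Builds the 2x2 table (overlapping the family / not) x (group A / group B)
#' and applies a two-sided Fisher's exact test. The odds ratio is the sample
#' cross-product (a*d)/(b*c); 0.5 is added to every cell only when some cell
#' is 0.
#'
#' @param groupA,groupB disjoint character vectors of transcript ids
#' @param overlaps output of [te_overlaps()]
#' @param family repeat family to test
#' @return list with `family`, `table` (2x2 matrix), `odds_ratio`, `p_value`
#' @export
family_enrichment <- function(groupA, groupB, overlaps, family) {
  if (!length(groupA) || !length(groupB))
    stopf("family_enrichment: empty group")
  if (length(intersect(groupA, groupB)))
    stopf("family_enrichment: groups must be disjoint")
  fam_ids <- unique(overlaps[overlaps$family == family]$transcript_id)
  a <- sum(groupA %in% fam_ids); b <- length(groupA) - a
  c_ <- sum(groupB %in% fam_ids); d <- length(groupB) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("groupA", "groupB"), c("overlap", "no_overlap")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  list(family = family, table = tab, odds_ratio = or, p_value = p)
}

#' Window density table
#'
#' Tiles each chromosome into windows of `window_bp` starting every
#' `step_bp` (default: non-overlapping tiling, step = width, the usual
#' Circos-track convention) and counts features by their start coordinate.
#' The last partial window is included; windows with zero features are
#' emitted. With the default tiling, per-chromosome counts sum to the number
#' of features (each start falls in exactly one window).
#'
#' @param features data.frame/data.table with `chrom` and `start`
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param window_bp window width (default 500 kb)
#' @param step_bp distance between window starts (default `window_bp`)
#' @return data.table (chrom, window_start, window_end, count)
#' @export
window_density <- function(features, chrom_lengths, window_bp = 500000L,
                           step_bp = window_bp) {
  if (window_bp <= 0 || step_bp <= 0)
    stopf("window_density: window_bp and step_bp must be positive")
  features <- data.table::as.data.table(features)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    ws <- seq.int(0L, max(0L, len - 1L), by = step_bp)
    starts <- features[chrom == ch]$start
    cnt <- vapply(ws, function(w) sum(starts >= w & starts < w + window_bp),
                  integer(1))
    data.table::data.table(chrom = ch, window_start = as.integer(ws),
                           window_end = as.integer(pmin(ws + window_bp, len)),
                           count = cnt)
  })
  data.table::rbindlist(out)
}
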
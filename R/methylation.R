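## Per-cytosine methylation levels, strand-oriented TSS metaprofiles per
## context, and up-/down-regulated group comparisons.

#' Per-site percent methylation
#'
#' `100 * meth / (meth + unmeth)`; zero-coverage sites are undefined (`NA`)
#' and excluded from averages rather than treated as 0%.
#'
#' @param meth_count,unmeth_count non-negative integer vectors
#' @return numeric vector of percentages in `[0, 100]`, `NA` where coverage is 0
#' @export
site_percent <- function(meth_count, unmeth_count) {
  if (any(meth_count < 0) || any(unmeth_count < 0))
    stopf("site_percent: negative counts")
  tot <- meth_count + unmeth_count
  ifelse(tot > 0, 100 * meth_count / tot, NA_real_)
}

## transcript-oriented TSS and signed offset of a site from it.
## TSS is the 5'-most transcribed base: span start on +, span end - 1 on -.
## Offsets are 5'->3' along the transcript: negative = upstream.
tss_of <- function(spans) {
  ifelse(spans$strand == "+", spans$start, spans$end - 1L)
}

#' Strand-oriented TSS methylation metaprofile
#'
#' Averages per-site percent methylation in fixed bins across a window
#' around each transcript's TSS, oriented 5'->3' (negative offsets are
#' upstream of the TSS on the transcript's own 5' side, so profiles from
#' both strands superimpose). Sites with read coverage below `min_coverage`
#' are excluded; a bin's mean is the unweighted mean of contributing site
#' percentages (each cytosine weighs the same, regardless of depth). Bins
#' with no contributing sites are `NA`, never 0.
#'
#' @param tx a [transcript_set] (or a span table from [tx_spans()])
#' @param records methylation records (see [read_methylation_report()])
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`
#' @param flank_bp half-window size; the profile tiles `[-flank, +flank)`
#' @param bin_bp bin width (must divide `flank_bp`)
#' @param min_coverage minimum reads (meth+unmeth) for a site to contribute
#' @return data.table (context, bin_start, bin_end, mean_pct, n_sites)
#' @export
tss_profile <- function(tx, records, context, flank_bp = 1000L, bin_bp = 50L,
                        min_coverage = 1L) {
  if (flank_bp %% bin_bp != 0L)
    stopf("tss_profile: flank_bp must be divisible by bin_bp")
  ctx <- context
  spans <- if ("n_exons" %in% names(tx)) data.table::as.data.table(tx) else tx_spans(tx)
  rec <- data.table::as.data.table(records)[context == ctx]
  rec <- rec[meth_count + unmeth_count >= min_coverage]
  rec[, pct := site_percent(meth_count, unmeth_count)]
  edges <- seq.int(-flank_bp, flank_bp, by = bin_bp)
  offs <- integer(0); pcts <- numeric(0)
  for (i in seq_len(nrow(spans))) {
    tss <- tss_of(spans[i])
    r <- rec[chrom == spans$chrom[i]]
    off <- if (spans$strand[i] == "+") r$pos - tss else tss - r$pos
    keep <- off >= -flank_bp & off < flank_bp
    offs <- c(offs, off[keep]); pcts <- c(pcts, r$pct[keep])
  }
  bin <- findInterval(offs, edges, rightmost.closed = FALSE)
  out <- data.table::data.table(
    context = ctx,
    bin_start = edges[-length(edges)],
    bin_end = edges[-1L],
    mean_pct = NA_real_, n_sites = 0L)
  if (length(bin)) {
    agg <- data.table::data.table(bin = bin, pct = pcts)[
      , .(mean_pct = mean(pct), n_sites = .N), by = bin]
    out[agg$bin, `:=`(mean_pct = agg$mean_pct, n_sites = agg$n_sites)]
  }
  out[]
}

#' Per-transcript mean methylation near the TSS
#'
#' The summary value used for group comparisons: the unweighted mean of
#' per-site percentages within the chosen side of the TSS window for each
#' transcript (default: upstream, `[-flank, 0)`).
#'
#' @inheritParams tss_profile
#' @param side `"upstream"`, `"downstream"` or `"both"`
#' @return named numeric vector, one value per transcript (`NA` when no
#'   covered site falls in the window)
#' @export
tss_region_levels <- function(tx, records, context, flank_bp = 1000L,
                              min_coverage = 1L,
                              side = c("upstream", "downstream", "both")) {
  side <- match.arg(side)
  ctx <- context
  spans <- if ("n_exons" %in% names(tx)) data.table::as.data.table(tx) else tx_spans(tx)
  rec <- data.table::as.data.table(records)[context == ctx]
  rec <- rec[meth_count + unmeth_count >= min_coverage]
  rec[, pct := site_percent(meth_count, unmeth_count)]
  lo <- if (side == "downstream") 0L else -flank_bp
  hi <- if (side == "upstream") 0L else flank_bp
  out <- vapply(seq_len(nrow(spans)), function(i) {
    tss <- tss_of(spans[i])
    r <- rec[chrom == spans$chrom[i]]
    off <- if (spans$strand[i] == "+") r$pos - tss else tss - r$pos
    v <- r$pct[off >= lo & off < hi]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  stats::setNames(out, spans$transcript_id)
}

#' Up-/down-regulated transcript groups between two stages
#'
#' `log2FC = log2((late + pc) / (early + pc))` on stage means; up is
#' `log2FC > 1`, down is `log2FC < -1`. The groups are disjoint by
#' construction.
#'
#' @param early_means,late_means named numeric vectors of stage-mean FPKM on
#'   a matched transcript set
#' @param pseudocount added before the log ratio
#' @return list with `up`, `down` (character vectors) and `log2fc`
#' @export
regulation_groups <- function(early_means, late_means, pseudocount = 1) {
  ids <- intersect(names(early_means), names(late_means))
  lfc <- log2((late_means[ids] + pseudocount) / (early_means[ids] + pseudocount))
  list(up = ids[lfc > 1], down = ids[lfc < -1], log2fc = lfc)
}

#' Compare two methylation level distributions
#'
#' Two-sample, two-sided Kolmogorov-Smirnov test on per-transcript mean
#' methylation levels (NAs dropped).
#'
#' @param groupA_levels,groupB_levels numeric vectors (e.g. from
#'   [tss_region_levels()])
#' @return list with `statistic` (max ECDF difference) and `p_value`
#' @export
compare_methylation <- function(groupA_levels, groupB_levels) {
  a <- groupA_levels[!is.na(groupA_levels)]
  b <- groupB_levels[!is.na(groupB_levels)]
  if (!length(a) || !length(b))
    stopf("compare_methylation: empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
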
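## Ripening-stage analysis: highly expressed sets, differential expression
## with BH-FDR, Venn partitioning of the three contrasts, nearest-mRNA
## pairing and pair correlation.

stage_samples <- function(design, stage_) {
  design <- data.table::as.data.table(design)
  s <- design[!is.na(stage) & stage == stage_]$sample_id
  if (!length(s)) stopf("stage '%s' not present in design", stage_)
  s
}

#' Highly expressed transcript set at a ripening stage
#'
#' Kept iff the mean FPKM across the stage's replicates is strictly above
#' `min_mean_fpkm` (default 10, the floor above which transcripts are
#' considered candidates for a role in ripening).
#'
#' @param mat FPKM matrix
#' @param design design table with a `stage` column
#' @param stage stage name (e.g. `"MG"`, `"BR"`, `"BR+7"`)
#' @param min_mean_fpkm mean-FPKM floor (strict >)
#' @return character vector of transcript ids
#' @export
expressed_set <- function(mat, design, stage, min_mean_fpkm = 10) {
  cols <- stage_samples(design, stage)
  m <- rowMeans(mat[, cols, drop = FALSE])
  rownames(mat)[m > min_mean_fpkm]
}

## exact (or sampled) replicate-label permutation p for a mean difference
perm_p <- function(a, b, n_max_exact = 10) {
  obs <- abs(mean(a) - mean(b))
  v <- c(a, b); nA <- length(a); n <- length(v)
  if (n <= n_max_exact) {
    idx <- utils::combn(n, nA)
    stat <- apply(idx, 2L, function(i) abs(mean(v[i]) - mean(v[-i])))
    mean(stat >= obs - 1e-12)
  } else {
    stat <- replicate(1000, {
      i <- sample.int(n, nA)
      abs(mean(v[i]) - mean(v[-i]))
    })
    (sum(stat >= obs - 1e-12) + 1) / (1000 + 1)
  }
}

welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b)$p.value
}

#' Differential expression between two ripening stages
#'
#' Fold change is computed on stage means with a pseudocount:
#' `log2fc = log2((meanA + pc) / (meanB + pc))`. The p-value comes from a
#' two-sided location test on `log2(FPKM + pc)` replicate values — by
#' default a Welch t-test; `method = "permutation"` uses an exact
#' replicate-label permutation (enumerated when the two stages have at most
#' 10 replicates in total, otherwise 1000 sampled relabelings). Externally
#' computed p-values can be injected via `external_p`. q-values are
#' Benjamini-Hochberg over all tested transcripts, and a transcript is
#' significant iff `|log2fc| > 1` and `q < 0.05`.
#'
#' @param mat FPKM matrix
#' @param design design table
#' @param contrast character vector of two stage names `c(A, B)`
#' @param pseudocount added to FPKM before logs and fold changes
#' @param method `"t"` (default) or `"permutation"`
#' @param external_p optional named numeric vector of p-values keyed by
#'   transcript id, bypassing the internal test
#' @param lfc_cut,q_cut significance cutoffs
#' @return data.table (transcript_id, contrast, log2fc, p, q, significant)
#' @export
de_test <- function(mat, design, contrast, pseudocount = 1,
                    method = c("t", "permutation"), external_p = NULL,
                    lfc_cut = 1, q_cut = 0.05) {
  method <- match.arg(method)
  colsA <- stage_samples(design, contrast[1L])
  colsB <- stage_samples(design, contrast[2L])
  mA <- rowMeans(mat[, colsA, drop = FALSE])
  mB <- rowMeans(mat[, colsB, drop = FALSE])
  lfc <- log2((mA + pseudocount) / (mB + pseudocount))
  la <- log2(mat[, colsA, drop = FALSE] + pseudocount)
  lb <- log2(mat[, colsB, drop = FALSE] + pseudocount)
  if (!is.null(external_p)) {
    p <- unname(external_p[rownames(mat)])
    if (anyNA(p)) stopf("de_test: external_p missing for some transcripts")
  } else {
    if (length(colsA) < 2L || length(colsB) < 2L)
      stopf("de_test: need >= 2 replicates per stage (or supply external_p)")
    test_fun <- if (method == "t") welch_p else function(a, b) perm_p(a, b)
    p <- vapply(seq_len(nrow(mat)),
                function(i) test_fun(la[i, ], lb[i, ]), numeric(1))
  }
  q <- stats::p.adjust(p, method = "BH")
  data.table::data.table(
    transcript_id = rownames(mat),
    contrast = paste0(contrast[1L], "-vs-", contrast[2L]),
    log2fc = lfc, p = p, q = q,
    significant = abs(lfc) > lfc_cut & q < q_cut)
}

#' Three-set Venn partition
#'
#' Counts of the 7 exclusive regions of three id sets; the counts sum to
#' `|A U B U C|`.
#'
#' @param A,B,C character vectors of ids
#' @return named integer vector `A_only`, `B_only`, `C_only`, `AB`, `AC`,
#'   `BC`, `ABC`
#' @export
venn_partition <- function(A, B, C) {
  A <- unique(A); B <- unique(B); C <- unique(C)
  ids <- unique(c(A, B, C))
  inA <- ids %in% A; inB <- ids %in% B; inC <- ids %in% C
  c(A_only = sum(inA & !inB & !inC),
    B_only = sum(!inA & inB & !inC),
    C_only = sum(!inA & !inB & inC),
    AB = sum(inA & inB & !inC),
    AC = sum(inA & !inB & inC),
    BC = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC))
}

#' Nearest mRNA for each query transcript
#'
#' Distance is the unsigned genomic gap between spans with half-open
#' arithmetic (`gap = startB - endA` when B lies downstream; 0 for
#' overlapping or book-ended spans), strand-ignorant. Ties go to the
#' lexicographically smallest mRNA id. Queries with no same-chromosome mRNA
#' get `NA` distance and are reported via a message.
#'
#' @param query_spans span table (see [tx_spans()]) for the query transcripts
#' @param mrna_spans span table for candidate mRNAs
#' @return data.table (transcript_id, mrna_id, distance_bp)
#' @export
nearest_mrna <- function(query_spans, mrna_spans) {
  q <- data.table::as.data.table(query_spans)
  m <- data.table::as.data.table(mrna_spans)
  out <- lapply(seq_len(nrow(q)), function(i) {
    cand <- m[chrom == q$chrom[i]]
    if (!nrow(cand))
      return(data.table::data.table(transcript_id = q$transcript_id[i],
                                    mrna_id = NA_character_,
                                    distance_bp = NA_integer_))
    gap <- pmax(0L, pmax(q$start[i], cand$start) - pmin(q$end[i], cand$end))
    best <- which(gap == min(gap))
    pick <- best[order(cand$transcript_id[best])][1L]
    data.table::data.table(transcript_id = q$transcript_id[i],
                           mrna_id = cand$transcript_id[pick],
                           distance_bp = as.integer(gap[pick]))
  })
  res <- data.table::rbindlist(out)
  if (anyNA(res$distance_bp))
    message(sprintf("nearest_mrna: %d quer(y/ies) with no same-chromosome mRNA",
                    sum(is.na(res$distance_bp))))
  res
}

#' Pair DE lncRNAs with nearby DE mRNAs and correlate their profiles
#'
#' Forms pairs where the nearest differentially expressed mRNA lies strictly
#' within `max_distance` of a differentially expressed lncRNA, and computes
#' the Pearson correlation of `log2(FPKM + pseudocount)` across all samples
#' of the ripening stages. Zero-variance profiles give `NA` correlation but
#' the pair is retained (flagged by the NA). The returned table carries an
#' attribute `frac_within_30kb`: the fraction of DE lncRNAs whose nearest DE
#' mRNA is closer than 30 kb.
#'
#' @param de_lnc_ids,de_mrna_ids ids significant in at least one contrast
#' @param lnc_spans,mrna_spans span tables
#' @param mat FPKM matrix
#' @param design design table (stage samples are used)
#' @param max_distance pairing threshold in bp (strict <; default 10 kb)
#' @param pseudocount added before logs
#' @return data.table (lnc_id, mrna_id, distance_bp, pearson_r)
#' @export
pair_and_correlate <- function(de_lnc_ids, de_mrna_ids, lnc_spans, mrna_spans,
                               mat, design, max_distance = 10000,
                               pseudocount = 1) {
  lnc_spans <- data.table::as.data.table(lnc_spans)
  mrna_spans <- data.table::as.data.table(mrna_spans)
  q <- lnc_spans[transcript_id %in% de_lnc_ids]
  m <- mrna_spans[transcript_id %in% de_mrna_ids]
  if (!nrow(q) || !nrow(m)) {
    out <- data.table::data.table(lnc_id = character(0), mrna_id = character(0),
                                  distance_bp = integer(0), pearson_r = numeric(0))
    data.table::setattr(out, "frac_within_30kb", NA_real_)
    return(out)
  }
  nn <- nearest_mrna(q, m)
  frac30 <- mean(nn$distance_bp < 30000, na.rm = TRUE)
  pairs <- nn[!is.na(distance_bp) & distance_bp < max_distance]
  design <- data.table::as.data.table(design)
  cols <- design[!is.na(stage)]$sample_id
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- log2(mat[pairs$transcript_id[i], cols] + pseudocount)
    y <- log2(mat[pairs$mrna_id[i], cols] + pseudocount)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  out <- data.table::data.table(lnc_id = pairs$transcript_id,
                                mrna_id = pairs$mrna_id,
                                distance_bp = pairs$distance_bp,
                                pearson_r = r)
  data.table::setattr(out, "frac_within_30kb", frac30)
  out
}
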
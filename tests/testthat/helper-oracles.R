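## Brute-force oracles, deliberately independent of the implementation:
## plain double loops and closed-form enumerations.

## O(n*m) exon overlap between two single-transcript exon tables
oracle_exon_overlap <- function(a, b, same_strand) {
  if (a$chrom[1] != b$chrom[1]) return(0L)
  sa <- a$strand[1]; sb <- b$strand[1]
  if (sa == "." || sb == ".") return(0L)
  if (same_strand && sa != sb) return(0L)
  if (!same_strand && sa == sb) return(0L)
  tot <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a$start[i], b$start[j]); hi <- min(a$end[i], b$end[j])
    if (hi > lo) tot <- tot + (hi - lo)
  }
  tot
}

## all-pairs minimum span gap (half-open): 0 when overlapping or book-ended
oracle_nearest <- function(qs, qe, qchrom, spans) {
  best_d <- NA_integer_; best_id <- NA_character_
  for (j in seq_len(nrow(spans))) {
    if (spans$chrom[j] != qchrom) next
    d <- max(0L, max(qs, spans$start[j]) - min(qe, spans$end[j]))
    if (is.na(best_d) || d < best_d ||
        (d == best_d && spans$transcript_id[j] < best_id)) {
      best_d <- d; best_id <- spans$transcript_id[j]
    }
  }
  list(id = best_id, d = best_d)
}

## per-transcript TE families by pairwise exon scan
oracle_te_overlap <- function(tx, tes, min_bp = 10) {
  ids <- unique(tx$transcript_id)
  out <- list()
  for (id in ids) {
    ex <- tx[tx$transcript_id == id, ]
    for (t in seq_len(nrow(tes))) {
      if (tes$chrom[t] != ex$chrom[1]) next
      tot <- 0L
      for (i in seq_len(nrow(ex))) {
        lo <- max(ex$start[i], tes$start[t]); hi <- min(ex$end[i], tes$end[t])
        if (hi > lo) tot <- tot + (hi - lo)
      }
      if (tot >= min_bp)
        out[[length(out) + 1]] <- data.frame(transcript_id = id,
                                             family = tes$family[t],
                                             overlap_bp = tot)
    }
  }
  if (!length(out)) return(data.frame(transcript_id = character(0),
                                      family = character(0),
                                      overlap_bp = integer(0)))
  do.call(rbind, out)
}

## two-sided Fisher exact p by hypergeometric tail enumeration over all
## tables with the observed margins (conventional 1+1e-7 relative slack)
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b          # row 1 total (group A)
  n <- c_ + d         # row 2 total
  k <- a + c_         # first column total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## max absolute ECDF difference by direct evaluation on the pooled support
oracle_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

## Benjamini-Hochberg by the textbook step-up rule
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m); out[o] <- pmin(q, 1)
  out
}

## expected ripening truth helpers (derived from the planted stage plan:
## fruit-expressed transcripts sit at 40 FPKM, the DE plan drops the
## contrasting stage(s) to 10)
truth_expressed <- function(truth, stage) {
  drop_plans <- switch(stage,
                       "MG" = c("up_BR", "up_BR7"),
                       "BR" = c("down_BR", "up_BR7"),
                       "BR+7" = c("down_BR", "down_BR7"))
  truth$transcript_id[truth$ripening_expressed & !(truth$de_plan %in% drop_plans)]
}

truth_regulation <- function(truth) {
  list(up = truth$transcript_id[truth$de_plan %in% c("up_BR", "up_BR7")],
       down = truth$transcript_id[truth$de_plan %in% c("down_BR", "down_BR7")])
}
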
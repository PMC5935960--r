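## The five-stage artifact filter cascade. Stage order is fixed:
## positional category rules (in classify) -> length -> homology (EST,
## housekeeping ncRNA) -> protein homology + coding potential -> expression.
## Every inequality is applied literally as printed: strict > for
## length/coverage/identity/alignment/FPKM, e-value cutoffs as e <= cutoff.

#' Filter thresholds
#'
#' Defaults are the pipeline's published values: minimum transcript length
#' 200 bp; EST removal at e <= 1e-10 AND coverage > 80% AND identity > 80%;
#' housekeeping-ncRNA removal at e <= 1e-10 AND identity > 90% AND alignment
#' > 22 bp; protein removal at e <= 1e-10 AND alignment > 50 (as-reported
#' units); coding-score cut 0 (score > 0 removed); expression floor FPKM > 1
#' in at least one sample.
#'
#' @param min_length_bp minimum exonic length kept
#' @param est,ncrna,protein per-database removal criteria (named lists)
#' @param coding_score_cut transcripts with score strictly above this are removed
#' @param min_fpkm,min_samples_over_fpkm expression floor
#' @return a `filter_thresholds` list
#' @export
filter_thresholds <- function(min_length_bp = 200,
                              est = list(max_e = 1e-10, min_coverage_pct = 80, min_identity_pct = 80),
                              ncrna = list(max_e = 1e-10, min_identity_pct = 90, min_alignment_bp = 22),
                              protein = list(max_e = 1e-10, min_alignment = 50),
                              coding_score_cut = 0,
                              min_fpkm = 1, min_samples_over_fpkm = 1) {
  th <- list(min_length_bp = min_length_bp, est = est, ncrna = ncrna,
             protein = protein, coding_score_cut = coding_score_cut,
             min_fpkm = min_fpkm, min_samples_over_fpkm = min_samples_over_fpkm)
  structure(th, class = "filter_thresholds")
}

#' Length filter
#'
#' Transcripts shorter than `min_length_bp` (summed exon length) are removed;
#' a transcript of exactly the minimum length is kept ("shorter than" is
#' strict).
#'
#' @param tx a [transcript_set]
#' @param min_length_bp threshold in bp
#' @return surviving [transcript_set]
#' @export
filter_length <- function(tx, min_length_bp = 200) {
  len <- tx_lengths(tx)
  tx_subset(tx, names(len)[len >= min_length_bp])
}

## per-database removal predicates, each a single hit meeting ALL criteria
hit_removes <- function(hits, th) {
  db <- hits$database
  rem <- logical(nrow(hits))
  i <- db == "EST"
  rem[i] <- hits$e_value[i] <= th$est$max_e &
    hits$query_coverage_pct[i] > th$est$min_coverage_pct &
    hits$identity_pct[i] > th$est$min_identity_pct
  i <- db == "ncRNA"
  rem[i] <- hits$e_value[i] <= th$ncrna$max_e &
    hits$identity_pct[i] > th$ncrna$min_identity_pct &
    hits$alignment_length[i] > th$ncrna$min_alignment_bp
  i <- db == "protein"
  rem[i] <- hits$e_value[i] <= th$protein$max_e &
    hits$alignment_length[i] > th$protein$min_alignment
  rem
}

#' Homology filter
#'
#' A transcript is removed iff any single hit against the selected databases
#' meets all of that database's criteria simultaneously (any-hit rule). Hits
#' referencing transcripts not in `ids` are ignored with a warning.
#'
#' @param ids character vector of candidate transcript ids
#' @param hits homology hit table (see [read_homology_hits()])
#' @param thresholds a [filter_thresholds()]
#' @param databases which databases to apply at this stage
#' @return list with `kept` ids and `removed` (named character vector of
#'   removal reasons)
#' @export
filter_homology <- function(ids, hits, thresholds = filter_thresholds(),
                            databases = c("EST", "ncRNA", "protein")) {
  hits <- hits[database %in% databases]
  unknown <- setdiff(unique(hits$query_id), ids)
  if (length(unknown))
    warning(sprintf("filter_homology: %d hit(s) reference unknown transcripts (e.g. '%s'); ignored",
                    length(unknown), unknown[1L]), call. = FALSE)
  hits <- hits[query_id %in% ids]
  rem <- hit_removes(hits, thresholds)
  removed_tab <- unique(hits[rem, .(query_id, database)])
  reasons <- removed_tab[, .(reason = paste0("homology:", paste(sort(unique(database)), collapse = "+"))),
                         by = query_id]
  removed <- stats::setNames(reasons$reason, reasons$query_id)
  list(kept = setdiff(ids, names(removed)), removed = removed)
}

#' ORF-based coding potential score
#'
#' A documented stand-in for an SVM coding-potential classifier, keeping its
#' decision boundary semantics (score > 0 flags coding). The longest open
#' reading frame (ATG to in-frame stop, inclusive, forward strand only —
#' transcripts are already oriented) is found over the three frames and
#' scored as `max(orf_aa / 100, orf_coverage / 0.5) - 1`, where
#' `orf_aa = orf_nt / 3` and `orf_coverage = orf_nt / sequence_nt`. A
#' sequence with no ORF scores -1. Precomputed scores from an external tool
#' can be supplied to [run_cascade()] instead.
#'
#' @param sequences character vector of nucleotide sequences over A,C,G,T,N
#' @return numeric vector of scores
#' @export
coding_potential_score <- function(sequences) {
  if (any(!nzchar(sequences)))
    stopf("coding_potential_score: empty sequence")
  vapply(toupper(sequences), function(s) {
    n <- nchar(s)
    orf <- longest_orf_nt(s)
    max(orf / 3 / 100, (orf / n) / 0.5) - 1
  }, numeric(1), USE.NAMES = !is.null(names(sequences)))
}

## longest ATG..stop ORF length in nt (stop codon included), 3 forward frames
longest_orf_nt <- function(s) {
  n <- nchar(s)
  best <- 0L
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (!length(starts) || starts[1L] > n - 2L) next
    codons <- substring(s, starts, starts + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    open_from <- NA_integer_
    for (k in seq_along(codons)) {
      if (is.na(open_from) && is_atg[k]) open_from <- k
      if (!is.na(open_from) && is_stop[k]) {
        best <- max(best, (k - open_from + 1L) * 3L)
        open_from <- NA_integer_
      }
    }
  }
  best
}

#' Expression filter
#'
#' Kept iff the number of samples with FPKM strictly above `min_fpkm` is at
#' least `min_samples`. Transcripts absent from the matrix are treated as
#' all-zero (and reported via a message).
#'
#' @param ids candidate transcript ids
#' @param mat FPKM matrix (transcripts x samples)
#' @param min_fpkm FPKM floor (strict >)
#' @param min_samples minimum number of samples over the floor
#' @return character vector of surviving ids
#' @export
filter_expression <- function(ids, mat, min_fpkm = 1, min_samples = 1) {
  absent <- setdiff(ids, rownames(mat))
  if (length(absent))
    message(sprintf("filter_expression: %d transcript(s) absent from matrix, treated as all-zero", length(absent)))
  present <- intersect(ids, rownames(mat))
  n_over <- rowSums(mat[present, , drop = FALSE] > min_fpkm)
  present[n_over >= min_samples]
}

#' Run the five-stage filter cascade
#'
#' Applies, in order: length, EST+ncRNA homology, protein homology plus
#' coding-potential score, and expression, to the non-discarded classified
#' transcripts, producing the surviving lncRNA table and an auditable
#' per-stage report.
#'
#' @param classified classification table from [classify_transcripts()]
#' @param tx the novel [transcript_set] (for lengths)
#' @param hits homology hit table
#' @param sequences named character vector of transcript sequences, or NULL
#'   when `coding_scores` is given
#' @param mat FPKM matrix
#' @param thresholds a [filter_thresholds()]
#' @param coding_scores optional named numeric vector of precomputed coding
#'   scores, overriding the built-in ORF heuristic
#' @return list with `lnc` (surviving classification table), `report`
#'   (data.table stage/input/removed/surviving), `reasons` (per-transcript
#'   removal reason) and `summary` (label counts and percentages)
#' @export
run_cascade <- function(classified, tx, hits, sequences, mat,
                        thresholds = filter_thresholds(), coding_scores = NULL) {
  reasons <- data.table::data.table(transcript_id = character(0),
                                    stage = character(0), reason = character(0))
  note <- function(ids, stage, reason) {
    if (length(ids))
      reasons <<- rbind(reasons, data.table::data.table(
        transcript_id = ids, stage = stage, reason = reason))
  }
  report <- list()
  tally <- function(stage, input, kept) {
    report[[length(report) + 1L]] <<- data.table::data.table(
      stage = stage, input = length(input), removed = length(input) - length(kept),
      surviving = length(kept))
  }

  cur <- classified[label != "discarded"]$transcript_id
  note(classified[label == "discarded"]$transcript_id, "category", "reference match")

  ## stage 2: length
  lens <- tx_lengths(tx)[cur]
  kept <- cur[lens >= thresholds$min_length_bp]
  note(setdiff(cur, kept), "length",
       sprintf("shorter than %d bp", thresholds$min_length_bp))
  tally("length", cur, kept); cur <- kept

  ## stage 3: EST + housekeeping ncRNA homology (hits on transcripts already
  ## removed upstream are silently irrelevant, not unknown)
  h <- filter_homology(cur, hits[query_id %in% cur], thresholds,
                       databases = c("EST", "ncRNA"))
  note(names(h$removed), "homology", unname(h$removed))
  tally("homology_est_ncrna", cur, h$kept); cur <- h$kept

  ## stage 4: protein homology + coding potential
  h <- filter_homology(cur, hits[query_id %in% cur], thresholds,
                       databases = "protein")
  scores <- if (is.null(coding_scores)) {
    if (is.null(sequences))
      stopf("run_cascade: either sequences or coding_scores must be provided")
    coding_potential_score(sequences[cur])
  } else coding_scores[cur]
  coding_flagged <- cur[!is.na(scores) & scores > thresholds$coding_score_cut]
  removed4 <- union(names(h$removed), coding_flagged)
  note(names(h$removed), "coding", unname(h$removed))
  note(setdiff(coding_flagged, names(h$removed)), "coding",
       sprintf("coding score > %g", thresholds$coding_score_cut))
  kept <- setdiff(cur, removed4)
  tally("protein_coding_potential", cur, kept); cur <- kept

  ## stage 5: expression
  kept <- filter_expression(cur, mat, thresholds$min_fpkm,
                            thresholds$min_samples_over_fpkm)
  note(setdiff(cur, kept), "expression",
       sprintf("FPKM > %g in fewer than %d sample(s)", thresholds$min_fpkm,
               thresholds$min_samples_over_fpkm))
  tally("expression", cur, kept); cur <- kept

  lnc <- classified[transcript_id %in% cur]
  counts <- table(factor(lnc$label, levels = c("lincRNA", "ancRNA", "slncRNA", "intronic")))
  summary <- data.table::data.table(
    label = names(counts), count = as.integer(counts),
    pct = category_percentages(as.integer(counts)))
  list(lnc = lnc, report = data.table::rbindlist(report),
       reasons = reasons, summary = summary)
}

#' Category percentages at one decimal
#'
#' Percentages of total, rounded half away from zero to one decimal — the
#' reporting convention under which counts 70,635 / 8,085 / 602 print as
#' 89.0 / 10.2 / 0.8.
#'
#' @param counts non-negative numeric vector
#' @return numeric vector of percentages (NaN-free only when `sum(counts) > 0`)
#' @export
category_percentages <- function(counts) {
  round_half_up(100 * counts / sum(counts), 1)
}
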
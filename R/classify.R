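## Positional classification of novel transcripts against a coding reference.
##
## Categories follow the standard positional taxonomy: lincRNA (no exon
## overlap with coding genes), ancRNA (exon overlap on the opposite strand
## only), slncRNA (partial same-strand exon overlap, the assembler class-code
## "o" situation), intronic (span entirely inside one reference intron), and
## discarded (same-strand reference match: identical intron chain or full
## containment within reference exons). Precedence when several geometric
## conditions hold: sense evidence first, then antisense, then intronic,
## then intergenic — sense-exonic overlap is the strongest claim of relation
## to a gene and keeps the categories a disjoint partition.

#' Exonic overlap between two transcripts, in base pairs
#'
#' Sums intersection lengths over exon pairs; because exons within a
#' transcript are disjoint, every genomic base is counted at most once.
#' Transcripts on different chromosomes overlap by 0 by contract (not an
#' error). `same_strand = TRUE` counts overlap only when the two transcripts
#' are on the same strand, `FALSE` only when on opposite strands; an
#' unstranded party never satisfies either condition.
#'
#' @param a,b single-transcript [transcript_set]s (or their exon tables)
#' @param same_strand logical strand condition
#' @return non-negative integer overlap in bp
#' @export
exon_overlap_bp <- function(a, b, same_strand) {
  if (a$chrom[1L] != b$chrom[1L]) return(0L)
  sa <- a$strand[1L]; sb <- b$strand[1L]
  if (sa == "." || sb == ".") return(0L)
  if (same_strand != (sa == sb)) return(0L)
  ## exons disjoint within each transcript: pairwise pmin/pmax cross sum
  ov <- outer(a$end, b$end, pmin) - outer(a$start, b$start, pmax)
  sum(ov[ov > 0L])
}

## union of exon bases of `inner` covered by exons of `outer` (same chrom);
## TRUE if every base of `inner` lies within `outer`'s exons
contained_in_exons <- function(inner, outer) {
  for (i in seq_len(nrow(inner))) {
    s <- inner$start[i]; e <- inner$end[i]
    cov <- outer[end > s & start < e][order(start)]
    if (!nrow(cov)) return(FALSE)
    pos <- s
    for (j in seq_len(nrow(cov))) {
      if (cov$start[j] > pos) return(FALSE)
      pos <- max(pos, cov$end[j])
      if (pos >= e) break
    }
    if (pos < e) return(FALSE)
  }
  TRUE
}

## identical splice-junction chains; only meaningful when both have introns
same_intron_chain <- function(a, b) {
  ia <- a[order(start)]; ib <- b[order(start)]
  if (nrow(ia) < 2L || nrow(ib) < 2L || nrow(ia) != nrow(ib)) return(FALSE)
  all(ia$end[-nrow(ia)] == ib$end[-nrow(ib)]) &&
    all(ia$start[-1L] == ib$start[-1L])
}

#' Classify one novel transcript against the reference
#'
#' @param t a single-transcript [transcript_set] with strand `+` or `-`
#' @param reference a coding [transcript_set]
#' @return list with `transcript_id`, `label`, `evidence` (reference
#'   transcript ids) and `overlap_bp`
#' @export
classify_transcript <- function(t, reference) {
  if (t$strand[1L] == ".")
    stopf("classify_transcript: transcript '%s' is unstranded; exclude unstranded transcripts before classification",
          t$transcript_id[1L])
  ref_here <- reference[chrom == t$chrom[1L]]
  ref_ids <- unique(ref_here$transcript_id)
  sense_ids <- character(0); sense_bp <- integer(0)
  anti_ids <- character(0); anti_bp <- integer(0)
  matched <- character(0)
  for (rid in ref_ids) {
    r <- ref_here[transcript_id == rid]
    so <- exon_overlap_bp(t, r, same_strand = TRUE)
    if (so > 0L) {
      if (same_intron_chain(t, r) || contained_in_exons(t, r)) {
        matched <- c(matched, rid)
      } else {
        sense_ids <- c(sense_ids, rid); sense_bp <- c(sense_bp, so)
      }
    }
    ao <- exon_overlap_bp(t, r, same_strand = FALSE)
    if (ao > 0L) { anti_ids <- c(anti_ids, rid); anti_bp <- c(anti_bp, ao) }
  }
  if (length(matched))
    return(list(transcript_id = t$transcript_id[1L], label = "discarded",
                evidence = matched, overlap_bp = NA_integer_))
  if (length(sense_ids))
    return(list(transcript_id = t$transcript_id[1L], label = "slncRNA",
                evidence = sense_ids, overlap_bp = sum(sense_bp)))
  if (length(anti_ids))
    return(list(transcript_id = t$transcript_id[1L], label = "ancRNA",
                evidence = anti_ids, overlap_bp = sum(anti_bp)))
  ## intronic: span entirely within a single reference intron, any strand
  sp_s <- min(t$start); sp_e <- max(t$end)
  introns <- tx_introns(ref_here)
  if (nrow(introns)) {
    host <- introns[start <= sp_s & end >= sp_e]
    if (nrow(host))
      return(list(transcript_id = t$transcript_id[1L], label = "intronic",
                  evidence = unique(host$transcript_id), overlap_bp = 0L))
  }
  list(transcript_id = t$transcript_id[1L], label = "lincRNA",
       evidence = character(0), overlap_bp = 0L)
}

#' Classify all stranded novel transcripts
#'
#' Unstranded transcripts must be removed first (see [unstranded_ids()]);
#' their presence is an error, mirroring the pipeline rule that only
#' transcripts with strand assignments are considered.
#'
#' @param novel a [transcript_set] of novel transcripts
#' @param reference a coding [transcript_set]
#' @return data.table with columns `transcript_id`, `label`, `evidence`
#'   (comma-separated reference ids, empty for lincRNA) and `overlap_bp`
#' @export
classify_transcripts <- function(novel, reference) {
  uns <- unstranded_ids(novel)
  if (length(uns))
    stopf("classify_transcripts: %d unstranded transcript(s) present (e.g. '%s'); exclude them first",
          length(uns), uns[1L])
  ids <- unique(novel$transcript_id)
  res <- lapply(ids, function(id) {
    cl <- classify_transcript(tx_subset(novel, id), reference)
    data.table::data.table(transcript_id = cl$transcript_id, label = cl$label,
                           evidence = paste(sort(cl$evidence), collapse = ","),
                           overlap_bp = cl$overlap_bp)
  })
  data.table::rbindlist(res)
}
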
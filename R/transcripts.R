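#' Transcript sets
#'
#' A `transcript_set` is the package's container for exon-structured,
#' stranded transcript models. It is a `data.table` with one row per exon and
#' columns `transcript_id`, `gene_id`, `chrom`, `start`, `end`, `strand`,
#' `biotype`. All coordinates are 0-based half-open; conversion from 1-based
#' formats (GTF/GFF3) happens only in the readers. Exons of a transcript are
#' sorted by `start` and must be pairwise non-overlapping and on a single
#' chromosome/strand. `strand` is one of `"+"`, `"-"`, `"."`; `"."` marks
#' transcripts assembled from non-strand-specific data, which are carried but
#' excluded from positional classification.
#'
#' @param exons data.frame/data.table with the columns above (`gene_id` and
#'   `biotype` optional; default `biotype` is `"novel"`)
#' @return a `transcript_set` (keyed data.table)
#' @export
transcript_set <- function(exons) {
  x <- data.table::as.data.table(exons)
  if (!"gene_id" %in% names(x)) x[, gene_id := transcript_id]
  if (!"biotype" %in% names(x)) x[, biotype := "novel"]
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand", "biotype")
  miss <- setdiff(req, names(x))
  if (length(miss)) stopf("transcript_set: missing columns: %s", paste(miss, collapse = ", "))
  x <- x[, req, with = FALSE]
  x[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (any(x$start < 0L) || any(x$start >= x$end))
    stopf("transcript_set: intervals must satisfy 0 <= start < end")
  if (!all(x$strand %in% c("+", "-", ".")))
    stopf("transcript_set: strand must be one of '+', '-', '.'")
  data.table::setorder(x, transcript_id, start)
  bad <- x[, .(multi_chrom = data.table::uniqueN(chrom) > 1L,
               multi_strand = data.table::uniqueN(strand) > 1L,
               overlapping = any(start[-1L] < end[-.N])),
           by = transcript_id]
  if (any(bad$multi_chrom))
    stopf("transcript(s) with exons on multiple chromosomes: %s",
          paste(bad[multi_chrom == TRUE]$transcript_id, collapse = ", "))
  if (any(bad$multi_strand))
    stopf("transcript(s) with exons on multiple strands: %s",
          paste(bad[multi_strand == TRUE]$transcript_id, collapse = ", "))
  if (any(bad$overlapping))
    stopf("transcript(s) with overlapping exons: %s",
          paste(bad[overlapping == TRUE]$transcript_id, collapse = ", "))
  data.table::setattr(x, "class", c("transcript_set", class(data.table::data.table())))
  x
}

#' Per-transcript spans
#'
#' Collapses a [transcript_set] to one row per transcript: the genomic span
#' (first exon start to last exon end), exon count and total exonic length.
#'
#' @param tx a [transcript_set]
#' @return data.table with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `biotype`, `n_exons`, `exonic_bp`
#' @export
tx_spans <- function(tx) {
  tx[, .(gene_id = gene_id[1L], chrom = chrom[1L],
         start = min(start), end = max(end),
         strand = strand[1L], biotype = biotype[1L],
         n_exons = .N, exonic_bp = sum(end - start)),
     by = transcript_id]
}

#' Per-transcript introns
#'
#' Gaps between consecutive exons, as 0-based half-open intervals.
#'
#' @param tx a [transcript_set]
#' @return data.table with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand` (empty for mono-exon transcripts)
#' @export
tx_introns <- function(tx) {
  tx[order(transcript_id, start),
     if (.N > 1L) .(chrom = chrom[1L], start = end[-.N], end = start[-1L],
                    strand = strand[1L]),
     by = transcript_id]
}

#' Total exonic length per transcript
#'
#' @param tx a [transcript_set]
#' @return named integer vector of summed exon lengths
#' @export
tx_lengths <- function(tx) {
  s <- tx[, .(len = sum(end - start)), by = transcript_id]
  stats::setNames(s$len, s$transcript_id)
}

#' Unstranded transcript ids in a set
#'
#' @param tx a [transcript_set]
#' @return character vector of transcript ids with strand `"."`
#' @export
unstranded_ids <- function(tx) unique(tx[strand == "."]$transcript_id)

## subset a transcript_set to the given transcript ids, preserving class
tx_subset <- function(tx, ids) {
  out <- tx[transcript_id %in% ids]
  data.table::setattr(out, "class", class(tx))
  out
}
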
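## Readers and writers for the standard formats the pipeline touches.
## All coordinates are normalized to 0-based half-open at this boundary and
## nowhere else: GTF/GFF3 and cytosine reports arrive 1-based, BED arrives
## 0-based half-open already.

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, '\\s+"([^"]*)"'), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, character(1))
}

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, character(1))
}

## Split 9-column GTF/GFF lines, with line-numbered errors on malformed input.
read_gxf_lines <- function(path, format) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) stopf("%s: no feature records in '%s'", format, path)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- lineno[which(nf != 9L)[1L]]
    stopf("malformed %s line %d in '%s': expected 9 tab-separated fields", format, bad, path)
  }
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  dt <- data.table::data.table(
    chrom = fields[[1L]], source = fields[[2L]], feature = fields[[3L]],
    start1 = suppressWarnings(as.integer(fields[[4L]])),
    end1 = suppressWarnings(as.integer(fields[[5L]])),
    score = fields[[6L]], strand = fields[[7L]], frame = fields[[8L]],
    attrs = fields[[9L]], lineno = lineno)
  bad <- which(is.na(dt$start1) | is.na(dt$end1) | dt$start1 < 1L | dt$end1 < dt$start1)
  if (length(bad))
    stopf("malformed %s line %d in '%s': invalid coordinates", format, dt$lineno[bad[1L]], path)
  bad <- which(!dt$strand %in% c("+", "-", "."))
  if (length(bad))
    stopf("malformed %s line %d in '%s': strand must be one of +, -, .",
          format, dt$lineno[bad[1L]], path)
  dt
}

#' Read assembled transcript models from a GTF file
#'
#' Parses `exon` features, groups them by `transcript_id` and returns a
#' [transcript_set] with coordinates converted from 1-based inclusive to the
#' internal 0-based half-open convention. Transcripts lacking a strand
#' (`"."`) are retained and flagged via [unstranded_ids()]; they are excluded
#' from classification by the caller, not silently dropped here.
#'
#' @param path GTF file; `exon` lines must carry `transcript_id` (and ideally
#'   `gene_id`) attributes
#' @param biotype biotype assigned to all transcripts (default `"novel"`)
#' @return a [transcript_set]
#' @export
read_gtf <- function(path, biotype = "novel") {
  dt <- read_gxf_lines(path, "GTF")
  dt <- dt[feature == "exon"]
  if (!nrow(dt)) stopf("GTF '%s' contains no exon features", path)
  tid <- gtf_attr(dt$attrs, "transcript_id")
  if (anyNA(tid))
    stopf("malformed GTF line %d in '%s': exon without transcript_id",
          dt$lineno[which(is.na(tid))[1L]], path)
  gid <- gtf_attr(dt$attrs, "gene_id")
  gid[is.na(gid)] <- tid[is.na(gid)]
  transcript_set(data.table::data.table(
    transcript_id = tid, gene_id = gid, chrom = dt$chrom,
    start = dt$start1 - 1L, end = dt$end1, strand = dt$strand,
    biotype = biotype))
}

#' Write a transcript set as GTF
#'
#' Emits one `exon` line per exon, converting back to 1-based inclusive
#' coordinates; `write_gtf(read_gtf(f))` is record-equivalent to `f`.
#'
#' @param tx a [transcript_set]
#' @param path output file
#' @param source value for the GTF source column
#' @param meta named list written as leading `#` comment lines
#' @return the path, invisibly
#' @export
write_gtf <- function(tx, path, source = "lncfruit", meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s = %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              character(1))), con)
  writeLines(sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    tx$chrom, source, tx$start + 1L, tx$end, tx$strand, tx$gene_id,
    tx$transcript_id), con)
  invisible(path)
}

#' Read a protein-coding reference annotation from GFF3
#'
#' Resolves the `gene`/`mRNA`/`exon` hierarchy through `ID`/`Parent`
#' attributes and keeps only exons whose parent is an `mRNA` feature; other
#' feature types (ncRNA_gene, tRNA, ...) are excluded. An `exon` whose
#' `Parent` does not resolve to any mRNA is an error.
#'
#' @param path GFF3 file
#' @return a [transcript_set] with `biotype = "coding"`
#' @export
read_reference_gff3 <- function(path) {
  dt <- read_gxf_lines(path, "GFF3")
  mrna <- dt[feature %in% c("mRNA", "transcript")]
  mrna_id <- gff3_attr(mrna$attrs, "ID")
  if (anyNA(mrna_id))
    stopf("malformed GFF3 line %d in '%s': mRNA without ID",
          mrna$lineno[which(is.na(mrna_id))[1L]], path)
  mrna_gene <- gff3_attr(mrna$attrs, "Parent")
  mrna_gene[is.na(mrna_gene)] <- mrna_id[is.na(mrna_gene)]
  ## restrict to protein-coding mRNAs only
  keep <- mrna$feature == "mRNA"
  mrna_id <- mrna_id[keep]; mrna_gene <- mrna_gene[keep]
  ex <- dt[feature == "exon"]
  if (!nrow(ex)) stopf("GFF3 '%s' contains no exon features", path)
  parent <- gff3_attr(ex$attrs, "Parent")
  if (anyNA(parent))
    stopf("orphan exon at GFF3 line %d in '%s': exon without Parent",
          ex$lineno[which(is.na(parent))[1L]], path)
  known <- unique(c(mrna_id, gff3_attr(dt[!feature %in% c("mRNA", "transcript", "exon")]$attrs, "ID")))
  orphan <- !vapply(strsplit(parent, ",", fixed = TRUE),
                    function(p) any(p %in% known), logical(1))
  if (any(orphan))
    stopf("orphan exon at GFF3 line %d in '%s': Parent '%s' not found",
          ex$lineno[which(orphan)[1L]], path, parent[which(orphan)[1L]])
  ## keep exons parented by a coding mRNA (first matching parent wins)
  pmatch_ <- vapply(strsplit(parent, ",", fixed = TRUE), function(p) {
    hit <- p[p %in% mrna_id]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))
  ex <- ex[!is.na(pmatch_)]
  pmatch_ <- pmatch_[!is.na(pmatch_)]
  if (!nrow(ex)) stopf("GFF3 '%s': no exons belong to mRNA features", path)
  gene_of <- stats::setNames(mrna_gene, mrna_id)
  transcript_set(data.table::data.table(
    transcript_id = pmatch_, gene_id = unname(gene_of[pmatch_]),
    chrom = ex$chrom, start = ex$start1 - 1L, end = ex$end1,
    strand = ex$strand, biotype = "coding"))
}

#' Write a coding reference annotation as GFF3
#'
#' Emits a `gene`/`mRNA`/`exon` hierarchy readable by [read_reference_gff3()].
#'
#' @param tx a [transcript_set] (biotype `"coding"`)
#' @param path output file
#' @param meta named list written as leading `#` comment lines
#' @return the path, invisibly
#' @export
write_reference_gff3 <- function(tx, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(meta))
    writeLines(sprintf("# %s = %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              character(1))), con)
  sp <- tx_spans(tx)
  genes <- sp[, .(start = min(start), end = max(end), chrom = chrom[1L],
                  strand = strand[1L]), by = gene_id]
  out <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    out <- c(out, sprintf("%s\tlncfruit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                          g$chrom, g$start + 1L, g$end, g$strand, g$gene_id))
    gsp <- sp[gene_id == g$gene_id]
    for (j in seq_len(nrow(gsp))) {
      t <- gsp[j]
      out <- c(out, sprintf("%s\tlncfruit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                            t$chrom, t$start + 1L, t$end, t$strand,
                            t$transcript_id, g$gene_id))
      e <- tx[transcript_id == t$transcript_id]
      out <- c(out, sprintf("%s\tlncfruit\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                            e$chrom, e$start + 1L, e$end, e$strand,
                            t$transcript_id))
    }
  }
  writeLines(out, con)
  invisible(path)
}

#' Read a transposable-element track from BED6+1
#'
#' BED is already 0-based half-open; no coordinate conversion. Column 7 is
#' the repeat family (e.g. `LTR/Gypsy`, `Simple_repeat`) and must be
#' non-empty.
#'
#' @param path BED file with at least 7 columns
#' @return data.table with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `family`
#' @export
read_te_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 7L)
    stopf("TE BED '%s' must have >= 7 columns (column 7 = family)", path)
  dt <- dt[, 1:7]
  data.table::setnames(dt, c("chrom", "start", "end", "name", "score", "strand", "family"))
  dt[, `:=`(start = as.integer(start), end = as.integer(end),
            chrom = as.character(chrom), family = as.character(family))]
  if (any(!nzchar(dt$family)))
    stopf("TE BED '%s': empty family in column 7", path)
  if (any(dt$start < 0L | dt$start >= dt$end))
    stopf("TE BED '%s': intervals must satisfy 0 <= start < end", path)
  dt[]
}

#' Read a per-cytosine methylation report
#'
#' Tab-delimited columns `chrom`, `pos` (1-based), `strand`, `meth_count`,
#' `unmeth_count`, `context`; a header row is expected. Positions are
#' converted to 0-based; zero-coverage sites are retained. Any context other
#' than CG/CHG/CHH is an error.
#'
#' @param path report file
#' @return data.table with columns `chrom`, `pos` (0-based), `strand`,
#'   `meth_count`, `unmeth_count`, `context`
#' @export
read_methylation_report <- function(path) {
  dt <- read_tsv_meta(path)
  req <- c("chrom", "pos", "strand", "meth_count", "unmeth_count", "context")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stopf("methylation report '%s': missing columns: %s", path, paste(miss, collapse = ", "))
  bad <- which(!dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad))
    stopf("methylation report '%s': unknown context '%s' at record %d",
          path, dt$context[bad[1L]], bad[1L])
  if (any(!dt$strand %in% c("+", "-")))
    stopf("methylation report '%s': strand must be + or -", path)
  if (any(dt$meth_count < 0L) || any(dt$unmeth_count < 0L))
    stopf("methylation report '%s': negative counts", path)
  dt[, pos := as.integer(pos) - 1L]
  if (any(dt$pos < 0L)) stopf("methylation report '%s': position < 1", path)
  dt[, .(chrom = as.character(chrom), pos, strand, meth_count = as.integer(meth_count),
         unmeth_count = as.integer(unmeth_count), context)]
}

#' Read a homology hit table
#'
#' Tab-delimited with a header row: `query_id`, `database` (one of `EST`,
#' `ncRNA`, `protein`), `e_value`, `identity_pct`, `alignment_length`,
#' `query_coverage_pct`. Bounds are validated.
#'
#' @param path hit table file
#' @return data.table of hits
#' @export
read_homology_hits <- function(path) {
  dt <- read_tsv_meta(path)
  req <- c("query_id", "database", "e_value", "identity_pct",
           "alignment_length", "query_coverage_pct")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stopf("hit table '%s': missing columns: %s", path, paste(miss, collapse = ", "))
  if (any(!dt$database %in% c("EST", "ncRNA", "protein")))
    stopf("hit table '%s': database must be EST, ncRNA or protein", path)
  if (any(dt$e_value < 0))
    stopf("hit table '%s': negative e-value", path)
  if (any(dt$identity_pct < 0 | dt$identity_pct > 100) ||
      any(dt$query_coverage_pct < 0 | dt$query_coverage_pct > 100))
    stopf("hit table '%s': percentages must lie in [0, 100]", path)
  if (any(dt$alignment_length <= 0))
    stopf("hit table '%s': alignment_length must be positive", path)
  dt[]
}

#' Read an FPKM expression matrix
#'
#' Tab-delimited with a header row; first column `transcript_id`, remaining
#' columns one per sample.
#'
#' @param path matrix file
#' @return numeric matrix, transcripts in rows, samples in columns
#' @export
read_expression_matrix <- function(path) {
  dt <- read_tsv_meta(path)
  ids <- dt[[1L]]
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  if (any(m < 0)) stopf("expression matrix '%s': negative FPKM values", path)
  m
}

#' Read a sample design table
#'
#' Columns `sample_id`, `tissue`, `stage`, `replicate`; `tissue` or `stage`
#' may be empty/NA for samples outside that arm of the design.
#'
#' @param path design file
#' @return data.table
#' @export
read_design <- function(path) {
  dt <- read_tsv_meta(path)
  req <- c("sample_id", "tissue", "stage", "replicate")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stopf("design '%s': missing columns: %s", path, paste(miss, collapse = ", "))
  for (col in c("tissue", "stage"))
    dt[[col]][dt[[col]] %in% c("", "NA")] <- NA_character_
  dt[]
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file
#' @return named character vector of upper-case sequences
#' @export
read_transcript_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(s)), names(s))
}

#' Write transcript sequences as FASTA
#'
#' @param seqs named character vector
#' @param path output file
#' @return the path, invisibly
#' @export
write_transcript_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
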
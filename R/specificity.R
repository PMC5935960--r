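## Shannon-entropy tissue-specificity scoring.
##
## For transcript i with per-tissue mean FPKM x_ij, relative frequencies
## p_ij = x_ij / sum_j x_ij and H_i = -sum_j p_ij * log2(p_ij) (0*log 0 = 0).
## H ranges from 0 (expression confined to one tissue) to log2(t)
## (perfectly uniform across t tissues); with the 18-tissue design the
## ceiling is log2(18) = 4.17 bits.

#' Per-tissue mean expression
#'
#' Arithmetic mean of replicate FPKM per tissue; samples without a tissue
#' assignment in the design (e.g. ripening-stage samples) are ignored.
#'
#' @param mat FPKM matrix (transcripts x samples)
#' @param design design table with `sample_id` and `tissue`
#' @return numeric matrix, transcripts x tissues
#' @export
tissue_means <- function(mat, design) {
  design <- data.table::as.data.table(design)
  d <- design[!is.na(tissue)]
  if (!nrow(d)) stopf("tissue_means: design assigns no samples to tissues")
  missing_samp <- setdiff(d$sample_id, colnames(mat))
  if (length(missing_samp))
    stopf("tissue_means: design sample(s) absent from matrix: %s",
          paste(utils::head(missing_samp, 3), collapse = ", "))
  tissues <- unique(d$tissue)
  out <- vapply(tissues, function(ti) {
    cols <- d[tissue == ti]$sample_id
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), tissues))
  out
}

#' Shannon entropy of an expression profile, in bits
#'
#' @param x non-negative numeric vector (or matrix with profiles in rows) of
#'   per-tissue mean expression, t >= 2 tissues
#' @return entropy in bits; `NA` (undefined) for an all-zero profile —
#'   never 0, since 0 means maximal specificity
#' @export
shannon_entropy <- function(x) {
  if (is.matrix(x)) return(apply(x, 1L, shannon_entropy))
  if (any(x < 0)) stopf("shannon_entropy: negative expression value")
  if (length(x) < 2L) stopf("shannon_entropy: need at least 2 tissues")
  s <- sum(x)
  if (s == 0) return(NA_real_)
  p <- x / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Categorize an entropy score
#'
#' `H < specific_max` is tissue-specific, `H > uniform_min` is uniform
#' (the published convention puts the uniform class at score > 3),
#' anything between is heterogeneous; undefined (NA) entropy maps to
#' `"undefined"`.
#'
#' @param H numeric vector of entropies (bits)
#' @param specific_max upper cutoff for the tissue-specific class
#' @param uniform_min lower cutoff for the uniform class
#' @return character vector of categories
#' @export
categorize_entropy <- function(H, specific_max = 1, uniform_min = 3) {
  out <- rep("heterogeneous", length(H))
  out[H < specific_max] <- "tissue-specific"
  out[H > uniform_min] <- "uniform"
  out[is.na(H)] <- "undefined"
  out
}

#' Tissue-specificity scores for all transcripts
#'
#' @param mat FPKM matrix
#' @param design design table
#' @param specific_max,uniform_min category cutoffs (see [categorize_entropy()])
#' @return data.table (transcript_id, H, category, t)
#' @export
tissue_specificity <- function(mat, design, specific_max = 1, uniform_min = 3) {
  tm <- tissue_means(mat, design)
  H <- shannon_entropy(tm)
  data.table::data.table(
    transcript_id = rownames(tm),
    H = as.numeric(H),
    category = categorize_entropy(H, specific_max, uniform_min),
    t = ncol(tm))
}
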
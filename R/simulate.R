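## Synthetic-data generator: a toy genome annotation with planted novel
## transcripts of every positional class, expression with planted
## specificity/DE structure, a TE track, homology-hit tables, transcript
## sequences and per-cytosine methylation reports -- plus a machine-readable
## truth table, so every downstream stage is testable without downloads.
##
## The generator's defaults are a stated world, not tuning knobs: 18 tissues
## (entropy ceiling log2(18) = 4.17 bits), ripening stages MG/BR/BR+7 with 3
## replicates, planted DE stage-mean ratio 4, ~180 novel transcripts. All
## geometry is deterministic given the config; the seed only drives category
## assignment shuffles and noise draws.

default_tissues <- function() c(
  "leaf", "root", "seed", "peel", "flesh", "embryo", "anther", "bud",
  "hypocotyl", "septum", "pericarp", "flower", "stem", "petiole", "sepal",
  "pollen", "meristem", "cotyledon")

#' Simulation configuration
#'
#' @param n_chroms number of chromosomes
#' @param chrom_length chromosome length in bp
#' @param n_coding_genes total coding genes (3 exons of 300 bp, 400 bp introns)
#' @param n_linc,n_anc,n_slnc,n_intronic,n_decoy planted novel transcripts per
#'   class; decoys are intergenic transcripts carrying protein homology and a
#'   long ORF, exercising the cascade's database stages
#' @param tissues tissue names (default 18, giving the 4.17-bit entropy ceiling)
#' @param tissue_reps replicates per tissue
#' @param stages ripening stage names, early to late
#' @param stage_reps replicates per stage
#' @param fpkm_dispersion lognormal sd of multiplicative expression noise
#'   (0 = noise-free)
#' @param meth_concentration beta-binomial concentration of methylation noise
#'   (`Inf` = noise-free: counts deterministic at the planted profile)
#' @param meth_coverage reads per cytosine site
#' @param meth_site_spacing distance between simulated cytosines (bp)
#' @param meth_flank_bp half-window of simulated sites around each TSS
#' @param frac_specific,frac_uniform planted specificity fractions (the rest
#'   are heterogeneous, spread over 3 tissues)
#' @param frac_de fraction of ripening-expressed novel transcripts planted as
#'   differentially expressed
#' @param seed RNG seed
#' @return a `sim_config` list (validated)
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 2000000L,
                       n_coding_genes = 40L,
                       n_linc = 60L, n_anc = 40L, n_slnc = 30L,
                       n_intronic = 20L, n_decoy = 30L,
                       tissues = default_tissues(), tissue_reps = 2L,
                       stages = c("MG", "BR", "BR+7"), stage_reps = 3L,
                       fpkm_dispersion = 0.1,
                       meth_concentration = Inf, meth_coverage = 100L,
                       meth_site_spacing = 25L, meth_flank_bp = 1000L,
                       frac_specific = 0.3, frac_uniform = 0.4,
                       frac_de = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_chroms, n_coding_genes, n_linc, n_anc, n_slnc, n_intronic, n_decoy)
  if (any(counts < 0)) stopf("sim_config: counts must be >= 0")
  if (n_chroms < 1L) stopf("sim_config: need at least one chromosome")
  if (max(n_anc, n_slnc, n_intronic) > n_coding_genes)
    stopf("sim_config: each of n_anc/n_slnc/n_intronic must be <= n_coding_genes (one host gene each)")
  genes_per_chrom <- ceiling(n_coding_genes / n_chroms)
  slot <- chrom_length / genes_per_chrom
  if (slot < 25000)
    stopf("sim_config: placement impossible: %d genes on %d bp chromosomes leaves %.0f bp per gene slot (< 25000); increase chrom_length or n_chroms",
          n_coding_genes, chrom_length, slot)
  intergenic_needed <- ceiling((n_linc + n_decoy) / n_coding_genes)
  if (intergenic_needed > 3L)
    stopf("sim_config: placement impossible: too many intergenic transcripts (%d) for %d gene slots; increase n_coding_genes or chrom_length",
          n_linc + n_decoy, n_coding_genes)
  structure(cfg, class = "sim_config")
}

## Coding gene geometry: 3 exons x 300 bp, introns 400 bp, span 1700 bp.
## Gene g (0-based) sits at slot g within its chromosome, offset 30000 from
## the slot start so upstream intergenic features have room.
coding_geometry <- function(config) {
  g <- seq_len(config$n_coding_genes) - 1L
  genes_per_chrom <- ceiling(config$n_coding_genes / config$n_chroms)
  chrom_i <- g %/% genes_per_chrom + 1L
  slot_i <- g %% genes_per_chrom
  slot_w <- floor(config$chrom_length / genes_per_chrom)
  start <- slot_i * slot_w + 30000L
  data.table::data.table(
    gene = g + 1L, chrom = paste0("chr", chrom_i), start = start,
    strand = ifelse(g %% 2L == 0L, "+", "-"),
    slot_start = slot_i * slot_w)
}

#' Simulate the toy genome annotation
#'
#' Places coding genes on a regular grid and plants novel transcripts of
#' every class with guaranteed geometry: lincRNAs and decoys intergenic
#' (zero exon overlap with any coding exon), ancRNAs overlapping one coding
#' exon on the opposite strand only, slncRNAs partially overlapping a coding
#' exon on the same strand (extending into the intron, so they are neither
#' contained in reference exons nor intron-chain matches), and intronic
#' transcripts entirely inside one coding intron. A TE track is planted so
#' that lincRNAs are enriched for `LTR/Gypsy` overlap relative to mRNAs.
#' Deterministic given `config` (byte-identical outputs for equal seeds).
#'
#' @param config a [sim_config()]
#' @return list with `reference` (coding [transcript_set]), `novel`
#'   ([transcript_set]), `te` (TE table), `truth` (truth table keyed by
#'   transcript id) and `chrom_lengths`
#' @export
simulate_genome <- function(config) {
  geom <- coding_geometry(config)
  exon_w <- 300L; intron_w <- 400L
  ## reference: 3 exons per gene
  ref <- geom[, {
    es <- start + (0:2) * (exon_w + intron_w)
    .(transcript_id = sprintf("mRNA%04d.1", gene),
      gene_id = sprintf("Gene%04d", gene),
      chrom = chrom, start = es, end = es + exon_w, strand = strand,
      biotype = "coding")
  }, by = gene][, gene := NULL]
  reference <- transcript_set(ref)

  novel_rows <- list()
  add <- function(id, chrom, strand, starts, ends, class) {
    novel_rows[[length(novel_rows) + 1L]] <<- data.table::data.table(
      transcript_id = id, gene_id = id, chrom = chrom,
      start = as.integer(starts), end = as.integer(ends), strand = strand,
      biotype = "novel", class = class)
  }
  flip <- function(s) ifelse(s == "+", "-", "+")

  ## ancRNA i: single 400 bp exon overlapping exon 2 of host gene i by 200 bp,
  ## on the opposite strand, extending into intron 1
  for (i in seq_len(config$n_anc)) {
    h <- geom[i]
    e2 <- h$start + (exon_w + intron_w)       # exon 2 start
    add(sprintf("ANC%04d", i), h$chrom, flip(h$strand),
        e2 - 200L, e2 + 200L, "ancRNA")
  }
  ## slncRNA i: single 450 bp exon, same strand, overlapping exon 1 by 150 bp
  ## and running 300 bp into intron 1
  for (i in seq_len(config$n_slnc)) {
    h <- geom[i]
    e1_end <- h$start + exon_w
    add(sprintf("SLN%04d", i), h$chrom, h$strand,
        e1_end - 150L, e1_end + 300L, "slncRNA")
  }
  ## intronic i: 300 bp inside intron 2 of host gene i (intron 2 is clear of
  ## the planted ancRNA, which reaches into intron 1)
  for (i in seq_len(config$n_intronic)) {
    h <- geom[i]
    i2_start <- h$start + 2L * exon_w + intron_w   # end of exon 2
    add(sprintf("INT%04d", i), h$chrom, h$strand,
        i2_start + 50L, i2_start + 350L, "intronic")
  }
  ## intergenic placements: lincRNAs (two exons, 400+300 bp, 200 bp intron)
  ## and decoys (single 600 bp exon) upstream of gene slots, far from exons
  slot_of <- function(k) geom[(k - 1L) %% config$n_coding_genes + 1L]
  tier_of <- function(k) (k - 1L) %/% config$n_coding_genes   # 0, 1, 2
  for (i in seq_len(config$n_linc)) {
    h <- slot_of(i)
    base <- h$slot_start + 2000L + tier_of(i) * 6000L
    add(sprintf("LNC%04d", i), h$chrom, ifelse(i %% 2L == 0L, "+", "-"),
        c(base, base + 600L), c(base + 400L, base + 900L), "lincRNA")
  }
  for (i in seq_len(config$n_decoy)) {
    h <- slot_of(i)
    base <- h$slot_start + 20000L + tier_of(i) * 3000L
    add(sprintf("DEC%04d", i), h$chrom, ifelse(i %% 2L == 0L, "-", "+"),
        base, base + 600L, "decoy_coding")
  }
  novel_all <- data.table::rbindlist(novel_rows)
  classes <- unique(novel_all[, .(transcript_id, class)])
  novel <- transcript_set(novel_all[, -"class"])

  ## TE track: Gypsy elements over ~60% of lincRNA first exons, ~20% of
  ## mRNA spans; Copia/Simple_repeat/Low_complexity background between genes
  te_rows <- list()
  add_te <- function(chrom, start, end, family) {
    te_rows[[length(te_rows) + 1L]] <<- data.table::data.table(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      name = family, score = 0L, strand = "+", family = family)
  }
  linc_sp <- tx_spans(tx_subset(novel, classes[class == "lincRNA"]$transcript_id))
  ref_sp <- tx_spans(reference)
  with_seed(config$seed + 101L, {
    if (nrow(linc_sp)) {
      n_hit <- floor(0.6 * nrow(linc_sp))
      hit <- sort(sample.int(nrow(linc_sp), n_hit))
      for (i in hit)
        add_te(linc_sp$chrom[i], linc_sp$start[i] + 50L,
               linc_sp$start[i] + 150L, "LTR/Gypsy")
    }
    n_hit <- floor(0.2 * nrow(ref_sp))
    if (n_hit > 0) {
      hit <- sort(sample.int(nrow(ref_sp), n_hit))
      for (i in hit)
        add_te(ref_sp$chrom[i], ref_sp$start[i] + 20L,
               ref_sp$start[i] + 120L, "LTR/Gypsy")
    }
  })
  ## deterministic background elements in free space of every slot
  bg_fams <- c("LTR/Copia", "Simple_repeat", "Low_complexity")
  for (i in seq_len(nrow(geom)))
    add_te(geom$chrom[i], geom$slot_start[i] + 26000L + (i %% 3L) * 300L,
           geom$slot_start[i] + 26000L + (i %% 3L) * 300L + 200L,
           bg_fams[i %% 3L + 1L])
  te <- data.table::rbindlist(te_rows)
  data.table::setorder(te, chrom, start)

  ## truth: class, planted specificity, DE plan, distance to nearest coding gene
  truth <- build_truth(classes, novel, ref_sp, config)
  chrom_lengths <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                                   paste0("chr", seq_len(config$n_chroms)))
  list(reference = reference, novel = novel, te = te, truth = truth,
       chrom_lengths = chrom_lengths)
}

## planted specificity categories, ripening-expression and DE plan
build_truth <- function(classes, novel, ref_sp, config) {
  truth <- data.table::copy(classes)
  n <- nrow(truth)
  n_spec <- floor(config$frac_specific * n)
  n_unif <- floor(config$frac_uniform * n)
  cats <- c(rep("tissue-specific", n_spec), rep("uniform", n_unif),
            rep("heterogeneous", n - n_spec - n_unif))
  with_seed(config$seed + 202L, {
    truth[, spec_category := sample(cats)]
    truth[, spec_tissue := sample(config$tissues, .N, replace = TRUE)]
    ## ripening arm: half of the novel transcripts are fruit-expressed
    truth[, ripening_expressed := sample(rep(c(TRUE, FALSE), length.out = .N))]
    de_plan <- c("up_BR", "down_BR", "up_BR7", "down_BR7")
    truth[, de_plan := "none"]
    idx <- which(truth$ripening_expressed)
    n_de <- floor(config$frac_de * length(idx))
    if (n_de > 0)
      truth$de_plan[sample(idx, n_de)] <- sample(de_plan, n_de, replace = TRUE)
  })
  ## distance to nearest coding gene span (brute force)
  sp <- tx_spans(novel)
  dist <- vapply(seq_len(nrow(sp)), function(i) {
    cand <- ref_sp[chrom == sp$chrom[i]]
    if (!nrow(cand)) return(NA_integer_)
    as.integer(min(pmax(0L, pmax(sp$start[i], cand$start) -
                          pmin(sp$end[i], cand$end))))
  }, integer(1))
  truth <- merge(truth, data.table::data.table(
    transcript_id = sp$transcript_id, dist_to_coding = dist),
    by = "transcript_id", sort = TRUE)
  truth
}

## planted per-stage mean FPKM for a transcript given its truth row.
## Fruit-expressed transcripts sit at 40 FPKM; a DE plan drops the
## contrasting stage to 10 (ratio 4, |log2FC| = 2 on raw means).
stage_means_planted <- function(de_plan, ripening_expressed, stages) {
  base <- if (ripening_expressed) 40 else 2
  m <- stats::setNames(rep(base, length(stages)), stages)
  if (de_plan == "up_BR")    m[stages[1L]] <- 10
  if (de_plan == "down_BR")  m[c(stages[2L], stages[3L])] <- 10
  if (de_plan == "up_BR7")   m[c(stages[1L], stages[2L])] <- 10
  if (de_plan == "down_BR7") m[stages[3L]] <- 10
  m
}

#' Simulate the expression matrix and design table
#'
#' Tissue samples encode the planted specificity category: tissue-specific
#' transcripts put all expression in one designated tissue (entropy 0),
#' uniform transcripts the same mean in every tissue (entropy log2(t)),
#' heterogeneous transcripts an equal mean in 3 designated tissues (entropy
#' log2(3), between the category cutoffs 1 and 3). Ripening-stage samples
#' encode the DE plan with planted stage-mean ratio 4. Replicate noise is
#' multiplicative lognormal with sd `fpkm_dispersion` (zeros stay exactly
#' zero); coding transcripts are uniformly expressed fruit genes.
#'
#' @param truth truth table from [simulate_genome()] (novel transcripts); a
#'   `reference` [transcript_set] may be supplied to add coding rows
#' @param config a [sim_config()]
#' @param reference optional coding [transcript_set]
#' @return list with `mat` (FPKM matrix) and `design` (data.table)
#' @export
simulate_expression <- function(truth, config, reference = NULL) {
  tissues <- config$tissues
  stages <- config$stages
  design <- rbind(
    data.table::data.table(
      sample_id = paste0(rep(tissues, each = config$tissue_reps), "_r",
                         seq_len(config$tissue_reps)),
      tissue = rep(tissues, each = config$tissue_reps),
      stage = NA_character_,
      replicate = rep(seq_len(config$tissue_reps), length(tissues))),
    data.table::data.table(
      sample_id = paste0(rep(gsub("\\+", "p", stages), each = config$stage_reps),
                         "_r", seq_len(config$stage_reps)),
      tissue = NA_character_,
      stage = rep(stages, each = config$stage_reps),
      replicate = rep(seq_len(config$stage_reps), length(stages))))

  ids <- truth$transcript_id
  mean_mat <- matrix(0, nrow = length(ids), ncol = nrow(design),
                     dimnames = list(ids, design$sample_id))
  base_tissue <- 20
  for (i in seq_along(ids)) {
    tr <- truth[i]
    tm <- stats::setNames(rep(0, length(tissues)), tissues)
    if (tr$spec_category == "tissue-specific") {
      tm[tr$spec_tissue] <- base_tissue
    } else if (tr$spec_category == "uniform") {
      tm[] <- base_tissue
    } else {
      k <- match(tr$spec_tissue, tissues)
      tm[(c(k, k + 1L, k + 2L) - 1L) %% length(tissues) + 1L] <- base_tissue
    }
    sm <- stage_means_planted(tr$de_plan, tr$ripening_expressed, stages)
    for (j in seq_len(nrow(design))) {
      mean_mat[i, j] <- if (!is.na(design$tissue[j])) tm[design$tissue[j]]
                        else sm[design$stage[j]]
    }
  }
  if (!is.null(reference)) {
    rids <- unique(reference$transcript_id)
    ref_mean <- matrix(base_tissue, nrow = length(rids), ncol = nrow(design),
                       dimnames = list(rids, design$sample_id))
    ## a third of coding genes are planted DE across ripening, for pairing
    k <- seq_along(rids) %% 3L == 0L
    stage_cols <- which(!is.na(design$stage))
    early_cols <- stage_cols[design$stage[stage_cols] == stages[1L]]
    ref_mean[k, early_cols] <- 10
    mean_mat <- rbind(mean_mat, ref_mean)
  }
  mat <- with_seed(config$seed + 303L, {
    if (config$fpkm_dispersion > 0) {
      noise <- matrix(exp(stats::rnorm(length(mean_mat), 0, config$fpkm_dispersion)),
                      nrow = nrow(mean_mat))
      mean_mat * noise
    } else mean_mat
  })
  dimnames(mat) <- dimnames(mean_mat)
  list(mat = mat, design = design)
}

## planted mean methylation percent at a signed TSS offset (bp, 5'->3').
## Integer-valued at multiples of 25 bp so the noise-free limit is exact.
planted_methylation_profile <- function(class, context, offset) {
  k <- pmax(0, offset) / 25          # downstream step index
  if (class == "coding") {
    switch(context,
           CG  = ifelse(offset < 0, 40, pmin(80, 40 + k)),
           CHG = ifelse(offset < 0, 30, pmax(5, 30 - k)),
           CHH = ifelse(offset < 0, 20, pmax(4, 20 - k)))
  } else {
    switch(context, CG = rep(70, length(offset)),
           CHG = rep(45, length(offset)), CHH = rep(30, length(offset)))
  }
}

#' Simulate a per-cytosine methylation report
#'
#' Emits cytosine sites at fixed spacing around the TSS of every coding
#' transcript and planted lincRNA, for all three contexts, with counts drawn
#' beta-binomially around a deterministic, strand-oriented planted profile:
#' coding CG rises downstream of the TSS while CHG/CHH fall, and lincRNAs
#' carry elevated flat levels in every context. With
#' `meth_concentration = Inf` the counts are exact and the recovered
#' metaprofile equals the planted profile bin for bin.
#'
#' @param reference coding [transcript_set]
#' @param novel novel [transcript_set]
#' @param truth truth table (identifies the planted lincRNAs)
#' @param config a [sim_config()]
#' @return methylation record data.table (0-based `pos`), plus attribute
#'   `n_per_transcript` (sites emitted per transcript per context)
#' @export
simulate_methylation <- function(reference, novel, truth, config) {
  spans <- rbind(
    tx_spans(reference)[, .(transcript_id, chrom, start, end, strand, class = "coding")],
    tx_spans(tx_subset(novel, truth[class == "lincRNA"]$transcript_id))[
      , .(transcript_id, chrom, start, end, strand, class = "lincRNA")])
  offs <- seq.int(-config$meth_flank_bp, config$meth_flank_bp - config$meth_site_spacing,
                  by = config$meth_site_spacing)
  N <- config$meth_coverage
  rows <- vector("list", nrow(spans))
  with_seed(config$seed + 404L, {
    for (i in seq_len(nrow(spans))) {
      tss <- if (spans$strand[i] == "+") spans$start[i] else spans$end[i] - 1L
      pos <- if (spans$strand[i] == "+") tss + offs else tss - offs
      ctx_rows <- lapply(c("CG", "CHG", "CHH"), function(ctx) {
        p <- planted_methylation_profile(spans$class[i], ctx, offs) / 100
        meth <- if (is.infinite(config$meth_concentration)) {
          as.integer(round(N * p))
        } else {
          pp <- stats::rbeta(length(p), p * config$meth_concentration,
                             (1 - p) * config$meth_concentration)
          stats::rbinom(length(p), N, pp)
        }
        data.table::data.table(chrom = spans$chrom[i], pos = as.integer(pos),
                               strand = spans$strand[i], meth_count = meth,
                               unmeth_count = N - meth, context = ctx)
      })
      rows[[i]] <- data.table::rbindlist(ctx_rows)
    }
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, chrom, pos, context)
  data.table::setattr(out, "n_per_transcript", length(offs))
  out
}

## homology-hit table: decoys get removing protein hits (every third decoy
## also a removing EST hit); a sprinkling of sub-threshold hits on planted
## lncRNAs exercises the keep side of every inequality.
simulate_hits <- function(truth) {
  rows <- list()
  dec <- truth[class == "decoy_coding"]$transcript_id
  for (i in seq_along(dec)) {
    rows[[length(rows) + 1L]] <- data.table::data.table(
      query_id = dec[i], database = "protein", e_value = 1e-20,
      identity_pct = 95, alignment_length = 180, query_coverage_pct = 90)
    if (i %% 3L == 0L)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        query_id = dec[i], database = "EST", e_value = 1e-15,
        identity_pct = 92, alignment_length = 500, query_coverage_pct = 95)
  }
  lnc <- truth[class != "decoy_coding"]$transcript_id
  sub <- lnc[seq_along(lnc) %% 5L == 0L]
  for (i in seq_along(sub)) {
    rows[[length(rows) + 1L]] <- switch(
      (i %% 3L) + 1L,
      data.table::data.table(query_id = sub[i], database = "EST",
                             e_value = 1e-11, identity_pct = 80,
                             alignment_length = 300, query_coverage_pct = 85),
      data.table::data.table(query_id = sub[i], database = "ncRNA",
                             e_value = 1e-12, identity_pct = 95,
                             alignment_length = 22, query_coverage_pct = 50),
      data.table::data.table(query_id = sub[i], database = "protein",
                             e_value = 1e-5, identity_pct = 90,
                             alignment_length = 120, query_coverage_pct = 60))
  }
  if (!length(rows))
    return(data.table::data.table(query_id = character(0), database = character(0),
                                  e_value = numeric(0), identity_pct = numeric(0),
                                  alignment_length = integer(0),
                                  query_coverage_pct = numeric(0)))
  data.table::rbindlist(rows)
}

## transcript sequences matching exonic lengths: planted lncRNAs have no ATG
## (alphabet C/G/T) so the ORF score is -1; decoys are one long ORF.
simulate_sequences <- function(novel, truth, config) {
  lens <- tx_lengths(novel)
  with_seed(config$seed + 505L, {
    out <- vapply(names(lens), function(id) {
      n <- lens[[id]]
      cls <- truth[transcript_id == id]$class
      if (length(cls) && cls == "decoy_coding") {
        n_codons <- floor(n / 3) - 2L
        paste0("ATG", strrep("GCT", n_codons), "TAA",
               strrep("C", n - 3L * (n_codons + 2L)))
      } else {
        paste(sample(c("C", "G", "T"), n, replace = TRUE), collapse = "")
      }
    }, character(1))
  })
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes every input the pipeline reads -- reference GFF3, novel GTF, TE
#' BED, homology hits, transcript FASTA, FPKM matrix, design table,
#' methylation report -- plus the truth table and a key=value config dump,
#' all headed by comments recording the seed. Deterministic given the
#' config.
#'
#' @param config a [sim_config()]
#' @param dir output directory (created if needed)
#' @return named list of file paths plus the in-memory objects, invisibly
#' @export
simulate_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- simulate_genome(config)
  expr <- simulate_expression(g$truth, config, reference = g$reference)
  meth <- simulate_methylation(g$reference, g$novel, g$truth, config)
  hits <- simulate_hits(g$truth)
  seqs <- simulate_sequences(g$novel, g$truth, config)
  meta <- list(generator = "lncfruit", seed = config$seed)
  p <- list(
    reference = file.path(dir, "reference.gff3"),
    novel = file.path(dir, "novel.gtf"),
    te = file.path(dir, "te.bed"),
    truth = file.path(dir, "truth.tsv"),
    fpkm = file.path(dir, "fpkm.tsv"),
    design = file.path(dir, "design.tsv"),
    hits = file.path(dir, "hits.tsv"),
    fasta = file.path(dir, "transcripts.fa"),
    methylation = file.path(dir, "methylation.tsv"),
    config = file.path(dir, "config.txt"))
  write_reference_gff3(g$reference, p$reference, meta = meta)
  write_gtf(g$novel, p$novel, meta = meta)
  data.table::fwrite(g$te, p$te, sep = "\t", col.names = FALSE)
  write_tsv_meta(g$truth, p$truth, meta = meta)
  fp <- data.table::data.table(transcript_id = rownames(expr$mat))
  fp <- cbind(fp, data.table::as.data.table(expr$mat))
  write_tsv_meta(fp, p$fpkm, meta = meta)
  write_tsv_meta(expr$design, p$design, meta = meta)
  write_tsv_meta(hits, p$hits, meta = meta)
  write_transcript_fasta(seqs, p$fasta)
  meth_out <- data.table::copy(meth)[, pos := pos + 1L]  # report is 1-based
  write_tsv_meta(meth_out, p$methylation, meta = meta)
  writeLines(c(sprintf("# lncfruit simulation config"),
               paste0(names(config), " = ",
                      vapply(config, function(v) paste(format(v), collapse = ","),
                             character(1)))), p$config)
  invisible(c(p, list(genome = g, expression = expr, methylation = meth,
                      hit_table = hits, sequences = seqs)))
}
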
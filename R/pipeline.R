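## End-to-end orchestration: simulate (optional) -> classify -> filter ->
## repeats -> specificity -> ripening -> methylation, with one summary
## report and deterministic outputs given (config, seed).

#' Pipeline configuration
#'
#' Collects input/output paths and every stage's knobs. Defaults equal the
#' published values wherever one exists (see [filter_thresholds()],
#' [categorize_entropy()], [de_test()], [tss_profile()]).
#'
#' @param input_dir directory holding the inputs (as written by
#'   [simulate_dataset()]: reference.gff3, novel.gtf, te.bed, hits.tsv,
#'   transcripts.fa, fpkm.tsv, design.tsv, methylation.tsv)
#' @param output_dir directory for outputs (created)
#' @param simulate if TRUE, generate the inputs into `input_dir` first
#' @param sim a [sim_config()] used when `simulate = TRUE`
#' @param thresholds a [filter_thresholds()]
#' @param specific_max,uniform_min entropy category cutoffs
#' @param stages ripening stage names, early to late
#' @param min_mean_fpkm ripening expressed-set floor
#' @param pair_max_distance lincRNA-mRNA pairing threshold (bp)
#' @param meth_flank_bp,meth_bin_bp,meth_min_coverage TSS profile knobs
#' @param window_bp density window width
#' @param seed seed recorded in outputs and used for simulation
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(input_dir, output_dir,
                            simulate = FALSE, sim = sim_config(seed = seed),
                            thresholds = filter_thresholds(),
                            specific_max = 1, uniform_min = 3,
                            stages = c("MG", "BR", "BR+7"),
                            min_mean_fpkm = 10, pair_max_distance = 10000,
                            meth_flank_bp = 1000L, meth_bin_bp = 50L,
                            meth_min_coverage = 1L,
                            window_bp = 500000L, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes tab-delimited outputs (each with
#' a header comment recording version and seed) under
#' `config$output_dir`: `classification.tsv`, `lncrna.tsv`,
#' `filter_report.tsv`, `te_overlaps.tsv`, `density.tsv`, `entropy.tsv`,
#' `de.tsv`, `pairs.tsv`, `tss_profiles.tsv` and `summary.tsv`. Any stage
#' error aborts with the failing stage named.
#'
#' @param config a [pipeline_config()]
#' @return list of stage results, invisibly
#' @export
run_pipeline <- function(config) {
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  meta <- list(package = "lncfruit",
               version = as.character(utils::packageVersion("lncfruit")),
               seed = config$seed)
  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  inp <- function(f) file.path(config$input_dir, f)
  outp <- function(f) file.path(out_dir, f)

  if (isTRUE(config$simulate))
    stage_wrap("simulate", simulate_dataset(config$sim, config$input_dir))

  io <- stage_wrap("io", {
    for (f in c("reference.gff3", "novel.gtf", "te.bed", "hits.tsv",
                "transcripts.fa", "fpkm.tsv", "design.tsv", "methylation.tsv"))
      if (!file.exists(inp(f))) stopf("missing input '%s'", inp(f))
    list(reference = read_reference_gff3(inp("reference.gff3")),
         novel = read_gtf(inp("novel.gtf")),
         te = read_te_bed(inp("te.bed")),
         hits = read_homology_hits(inp("hits.tsv")),
         seqs = read_transcript_fasta(inp("transcripts.fa")),
         mat = read_expression_matrix(inp("fpkm.tsv")),
         design = read_design(inp("design.tsv")),
         meth = read_methylation_report(inp("methylation.tsv")))
  })

  cls <- stage_wrap("classify", {
    uns <- unstranded_ids(io$novel)
    stranded <- tx_subset(io$novel, setdiff(unique(io$novel$transcript_id), uns))
    classify_transcripts(stranded, io$reference)
  })
  write_tsv_meta(cls, outp("classification.tsv"), meta)

  casc <- stage_wrap("filter", run_cascade(
    cls, io$novel, io$hits, io$seqs, io$mat, config$thresholds))
  write_tsv_meta(casc$lnc, outp("lncrna.tsv"), meta)
  write_tsv_meta(casc$report, outp("filter_report.tsv"), meta)

  lnc_tx <- tx_subset(io$novel, casc$lnc$transcript_id)
  rep_res <- stage_wrap("repeats", {
    ov <- te_overlaps(lnc_tx, io$te)
    chrom_lengths <- tapply(c(io$te$end, io$novel$end, io$reference$end),
                            c(io$te$chrom, io$novel$chrom, io$reference$chrom), max)
    dens <- window_density(tx_spans(lnc_tx), chrom_lengths, config$window_bp)
    list(overlaps = ov, density = dens)
  })
  write_tsv_meta(rep_res$overlaps, outp("te_overlaps.tsv"), meta)
  write_tsv_meta(rep_res$density, outp("density.tsv"), meta)

  ent <- stage_wrap("specificity", tissue_specificity(
    io$mat[casc$lnc$transcript_id, , drop = FALSE], io$design,
    config$specific_max, config$uniform_min))
  write_tsv_meta(ent, outp("entropy.tsv"),
                 c(meta, list(specific_max = config$specific_max,
                              uniform_min = config$uniform_min)))

  rip <- stage_wrap("ripening", {
    st <- config$stages
    lnc_mat <- io$mat[casc$lnc$transcript_id, , drop = FALSE]
    mrna_ids <- unique(io$reference$transcript_id)
    mrna_mat <- io$mat[intersect(mrna_ids, rownames(io$mat)), , drop = FALSE]
    expressed <- lapply(st, function(s)
      expressed_set(lnc_mat, io$design, s, config$min_mean_fpkm))
    names(expressed) <- st
    contrasts <- list(c(st[1], st[2]), c(st[1], st[3]), c(st[2], st[3]))
    de_lnc <- data.table::rbindlist(lapply(contrasts, function(ct)
      de_test(lnc_mat, io$design, ct)))
    de_mrna <- data.table::rbindlist(lapply(contrasts, function(ct)
      de_test(mrna_mat, io$design, ct)))
    sig_sets <- lapply(unique(de_lnc$contrast), function(ct)
      de_lnc[contrast == ct & significant == TRUE]$transcript_id)
    venn <- venn_partition(sig_sets[[1]], sig_sets[[2]], sig_sets[[3]])
    pairs <- pair_and_correlate(
      unique(de_lnc[significant == TRUE]$transcript_id),
      unique(de_mrna[significant == TRUE]$transcript_id),
      tx_spans(lnc_tx), tx_spans(io$reference),
      io$mat, io$design, config$pair_max_distance)
    list(expressed = expressed, de_lnc = de_lnc, de_mrna = de_mrna,
         venn = venn, pairs = pairs)
  })
  write_tsv_meta(rip$de_lnc, outp("de.tsv"), meta)
  write_tsv_meta(rip$pairs, outp("pairs.tsv"),
                 c(meta, list(frac_within_30kb =
                                attr(rip$pairs, "frac_within_30kb"))))

  meth_res <- stage_wrap("methylation", {
    linc_ids <- casc$lnc[label == "lincRNA"]$transcript_id
    linc_tx <- tx_subset(io$novel, linc_ids)
    profs <- data.table::rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx) {
      rbind(cbind(tss_profile(io$reference, io$meth, ctx, config$meth_flank_bp,
                              config$meth_bin_bp, config$meth_min_coverage),
                  feature_class = "mRNA"),
            cbind(tss_profile(linc_tx, io$meth, ctx, config$meth_flank_bp,
                              config$meth_bin_bp, config$meth_min_coverage),
                  feature_class = "lincRNA"))
    }))
    st <- config$stages
    early <- rowMeans(io$mat[, stage_samples(io$design, st[1]), drop = FALSE])
    late <- rowMeans(io$mat[, stage_samples(io$design, st[length(st)]), drop = FALSE])
    groups <- regulation_groups(early, late)
    cg_levels <- tss_region_levels(
      rbind(io$reference, tx_subset(io$novel, linc_ids)), io$meth, "CG",
      config$meth_flank_bp, config$meth_min_coverage, side = "upstream")
    up_down <- if (length(groups$up) && length(groups$down)) {
      a <- cg_levels[intersect(groups$up, names(cg_levels))]
      b <- cg_levels[intersect(groups$down, names(cg_levels))]
      if (sum(!is.na(a)) && sum(!is.na(b))) compare_methylation(a, b) else NULL
    } else NULL
    list(profiles = profs, groups = groups, cg_levels = cg_levels,
         up_vs_down = up_down)
  })
  write_tsv_meta(meth_res$profiles, outp("tss_profiles.tsv"),
                 c(meta, list(flank_bp = config$meth_flank_bp,
                              bin_bp = config$meth_bin_bp)))

  summary <- stage_wrap("summary", {
    rbind(
      data.table::data.table(section = "category",
                             item = casc$summary$label,
                             value = sprintf("%d (%.1f%%)", casc$summary$count,
                                             casc$summary$pct)),
      data.table::data.table(section = "filter",
                             item = casc$report$stage,
                             value = sprintf("%d -> %d", casc$report$input,
                                             casc$report$surviving)),
      data.table::data.table(section = "entropy",
                             item = names(table(ent$category)),
                             value = as.character(as.vector(table(ent$category)))),
      data.table::data.table(section = "de",
                             item = unique(rip$de_lnc$contrast),
                             value = as.character(vapply(
                               unique(rip$de_lnc$contrast), function(ct)
                                 sum(rip$de_lnc[contrast == ct]$significant),
                               numeric(1)))),
      data.table::data.table(section = "pairs", item = "n_pairs",
                             value = as.character(nrow(rip$pairs))))
  })
  write_tsv_meta(summary, outp("summary.tsv"), meta)

  invisible(list(io = io, classification = cls, cascade = casc,
                 repeats = rep_res, entropy = ent, ripening = rip,
                 methylation = meth_res, summary = summary))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run-all` (and `classify` as a standalone step).
#' Used by the `exec/lncfruit` script; exposed for programmatic calls.
#'
#' @param args character vector of command-line arguments
#' @return exit status (0 on success), invisibly
#' @export
lncfruit_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: lncfruit <simulate|classify|run-all> [options]\n  simulate --out DIR [--seed N]\n  classify --novel X.gtf --reference Y.gff3 --out TABLE.tsv\n  run-all  --in DIR --out DIR [--seed N] [--simulate]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]; rest <- args[-1L]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i)) rest[i[1L] + 1L] else default
  }
  status <- tryCatch({
    switch(cmd,
      simulate = {
        out <- getopt("--out"); if (is.null(out)) stopf("simulate: --out required")
        seed <- as.integer(getopt("--seed", "1"))
        simulate_dataset(sim_config(seed = seed), out)
        0L
      },
      classify = {
        novel <- read_gtf(getopt("--novel"))
        reference <- read_reference_gff3(getopt("--reference"))
        stranded <- tx_subset(novel, setdiff(unique(novel$transcript_id),
                                             unstranded_ids(novel)))
        res <- classify_transcripts(stranded, reference)
        write_tsv_meta(res, getopt("--out", "classification.tsv"))
        0L
      },
      `run-all` = {
        seed <- as.integer(getopt("--seed", "1"))
        cfg <- pipeline_config(
          input_dir = getopt("--in"), output_dir = getopt("--out"),
          simulate = "--simulate" %in% rest, seed = seed,
          sim = sim_config(seed = seed))
        run_pipeline(cfg)
        0L
      },
      { message(usage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
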
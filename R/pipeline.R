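# Pipeline orchestration: the discovery screen (annotate -> DE -> DM ->
# DMR -> integrate) and the validation arm (BSP -> ROC -> survival), both
# file-based so any stage can be rerun in isolation, plus a machine-
# readable run manifest.

#' Pipeline parameter defaults
#'
#' Central location for every analysis threshold: FDR alpha 0.05, minimum
#' fold change 2, DMR cutoff 0.2 with at least 2 probes and 100 label
#' permutations, promoter window -2500/+1000 bp, probe-cluster gap 500 bp,
#' BSP conversion QC 0.95, median marker split.
#'
#' @param ... overrides of any default.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(alpha = 0.05, fc_min = 2, dmr_cutoff = 0.2, dmr_min_probes = 2L,
            dmr_resamples = 100L, dmr_max_gap = 500L,
            upstream = 2500L, downstream = 1000L,
            require_concordance = FALSE, qc_threshold = 0.95,
            min_clones = 10L, split_quantile = 0.5, seed = 1L)
  o <- list(...)
  unknown <- setdiff(names(o), names(p))
  if (length(unknown)) stop2("unknown parameter(s): %s",
                             paste(unknown, collapse = ", "))
  p[names(o)] <- o
  p
}

read_group_matrix <- function(path, samples_path, id_col) {
  df <- read_tsv_checked(path, required = id_col)
  mat <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(mat) <- df[[id_col]]
  sheet <- read_tsv_checked(samples_path, required = c("sample_id", "group"))
  if (!identical(colnames(mat), sheet$sample_id)) {
    sheet <- sheet[match(colnames(mat), sheet$sample_id), , drop = FALSE]
    if (anyNA(sheet$sample_id)) stop2("sample sheet does not cover %s", path)
  }
  list(mat = mat, group = sheet$group)
}

run_manifest <- function(out_dir, params, inputs, counts) {
  cfg_file <- tempfile()
  jsonlite::write_json(params, cfg_file, auto_unbox = TRUE, digits = NA)
  files <- unlist(inputs)
  files <- files[file.exists(files) & !dir.exists(files)]
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = params$seed,
    inputs = as.list(tools::md5sum(files)),
    counts = counts,
    version = as.character(utils::packageVersion("lncmeth")))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Run the discovery screen
#'
#' Stages: read manifest + GTF, build promoter windows and the probe-to-
#' promoter join, per-probe differential methylation, permutation DMR
#' calling, rank-test differential expression, and integration into
#' methylation-driven pairs with Spearman correlation annotation. Every
#' intermediate is persisted as TSV in `out_dir`; a `manifest.json` records
#' input checksums and per-stage record counts.
#'
#' @param inputs named list of paths: `manifest`, `gtf`, `beta`, `counts`,
#'   `samples`.
#' @param out_dir output directory.
#' @param params from [pipeline_params()].
#' @return invisible list with the main tables (`join`, `dm`, `dmrs`, `de`,
#'   `pairs`) and the run `manifest`.
#' @export
run_screen <- function(inputs, out_dir, params = pipeline_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message(sprintf("[screen %s] %s",
                                       format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)))
  msg("annotation: reading manifest and GTF")
  probes <- read_manifest(inputs$manifest)
  tx <- read_gtf_lnc(inputs$gtf)
  win <- promoter_windows(tx, params$upstream, params$downstream)
  join <- join_probes_to_promoters(probes, win)
  write_promoters_bed(win, file.path(out_dir, "promoters.bed"))
  write_tsv(join, file.path(out_dir, "join.tsv"))

  msg("methylation: per-probe screen and DMRs")
  bm <- read_group_matrix(inputs$beta, inputs$samples, "probe_id")
  dm <- probe_dm(bm$mat, bm$group, alpha = params$alpha)
  write_tsv(dm, file.path(out_dir, "dm_probes.tsv"))
  dmrs <- find_dmrs(bm$mat, bm$group, probes,
                    cutoff = params$dmr_cutoff,
                    min_probes = params$dmr_min_probes,
                    resamples = params$dmr_resamples,
                    max_gap = params$dmr_max_gap, seed = params$seed)
  write_tsv(dmrs, file.path(out_dir, "dmrs.tsv"))

  msg("expression: rank-test screen")
  cm <- read_group_matrix(inputs$counts, inputs$samples, "gene_id")
  de <- rank_test_de(cm$mat, cm$group, alpha = params$alpha,
                     fc_min = params$fc_min)
  write_tsv(de, file.path(out_dir, "de_genes.tsv"))

  msg("integration: calling methylation-driven pairs")
  pairs <- call_pairs(dm, de, join,
                      require_concordance = params$require_concordance)
  if (nrow(pairs)) {
    pairs <- correlate_pairs(pairs, bm$mat, cpm_normalize(cm$mat))
  }
  write_tsv(pairs, file.path(out_dir, "pairs.tsv"))
  if (nrow(pairs) == 0L) warning("empty pair set", call. = FALSE)

  counts <- list(probes = nrow(probes), transcripts = nrow(tx),
                 join_pairs = nrow(join), probes_tested = nrow(dm),
                 dm_significant = sum(dm$direction != "ns"),
                 dmrs = nrow(dmrs),
                 de_genes = sum(de$direction != "ns"),
                 pairs = nrow(pairs))
  manifest <- run_manifest(out_dir, params, inputs, counts)
  msg("done: %d pairs", nrow(pairs))
  invisible(list(join = join, dm = dm, dmrs = dmrs, de = de, pairs = pairs,
                 manifest = manifest))
}

#' Run the validation arm
#'
#' BSP clone calling and per-sample summaries, tumor-vs-normal group test
#' on the sample rates, ROC with Youden cut-off on the rates against the
#' tissue labels, and (when a clinical table is supplied) Kaplan-Meier
#' curves with a log-rank test after a median marker split. A missing
#' clinical file degrades gracefully to BSP + ROC only.
#'
#' @param inputs named list of paths: `bsp_ref`, `bsp_dir` (one FASTA of
#'   clones per sample), `bsp_sheet` (columns `sample_id`, `group`) and
#'   optionally `clinical` (columns `sample_id`, `time`, `event`, `marker`).
#' @param out_dir output directory.
#' @param params from [pipeline_params()].
#' @return invisible list with `samples` (per-sample rates), `group_test`,
#'   `roc`, `km` (per group), `logrank` and the run `manifest`.
#' @export
run_validation <- function(inputs, out_dir, params = pipeline_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message(sprintf("[validate %s] %s",
                                       format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)))
  msg("BSP: calling clones")
  ref_seqs <- read_fasta(inputs$bsp_ref)
  ref <- amplicon(names(ref_seqs)[1], ref_seqs[[1]])
  sheet <- read_tsv_checked(inputs$bsp_sheet,
                            required = c("sample_id", "group"))
  summaries <- list(); all_calls <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    fa <- file.path(inputs$bsp_dir, paste0(sid, ".fa"))
    seqs <- read_fasta(fa)
    calls <- lapply(names(seqs), function(cid) {
      call_clone(ref, seqs[[cid]], clone_id = cid,
                 qc_threshold = params$qc_threshold)
    })
    all_calls[[sid]] <- calls
    summaries[[sid]] <- withCallingHandlers(
      sample_summary(calls, sample_id = sid, group = sheet$group[i],
                     min_clones = params$min_clones),
      warning = function(w) { msg("%s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
  }
  sample_df <- data.frame(
    sample_id = vapply(summaries, `[[`, character(1), "sample_id"),
    group = vapply(summaries, `[[`, character(1), "group"),
    n_clones = vapply(summaries, function(x) as.integer(x$n_clones), integer(1)),
    rate = vapply(summaries, `[[`, numeric(1), "rate"),
    stringsAsFactors = FALSE)
  rownames(sample_df) <- NULL
  write_tsv(sample_df, file.path(out_dir, "bsp_samples.tsv"))
  lolli <- do.call(rbind, lapply(names(all_calls), function(sid) {
    m <- clone_matrix(all_calls[[sid]])
    data.frame(sample_id = sid, clone_id = rownames(m),
               calls = apply(m, 1, paste, collapse = ""),
               stringsAsFactors = FALSE)
  }))
  rownames(lolli) <- NULL
  write_tsv(lolli, file.path(out_dir, "bsp_lollipop.tsv"))

  msg("BSP: group comparison and ROC")
  gt <- compare_groups(sample_df)
  write_tsv(data.frame(statistic = gt$statistic, p = gt$p),
            file.path(out_dir, "bsp_group_test.tsv"))
  rc <- roc(sample_df$rate, sample_df$group == "tumor")
  yd <- youden(rc)
  write_tsv(data.frame(threshold = rc$thresholds, sens = rc$sens,
                       spec = rc$spec),
            file.path(out_dir, "roc_curve.tsv"))
  write_tsv(data.frame(auc = rc$auc, cutoff = yd$cutoff, youden_j = yd$j,
                       sens = yd$sens, spec = yd$spec),
            file.path(out_dir, "roc_summary.tsv"))

  km <- NULL; lr <- NULL
  if (!is.null(inputs$clinical) && file.exists(inputs$clinical)) {
    msg("survival: KM and log-rank by marker split")
    clin <- read_tsv_checked(inputs$clinical,
                             required = c("sample_id", "time", "event",
                                          "marker"))
    clin <- dichotomize(clin, quantile = params$split_quantile)
    km <- lapply(split(clin, clin$group), km_curve)
    for (g in names(km)) {
      write_tsv(km[[g]], file.path(out_dir, paste0("km_", g, ".tsv")))
    }
    lr <- logrank(clin)
    write_tsv(data.frame(chi_square = lr$chi_square, p = lr$p),
              file.path(out_dir, "logrank.tsv"))
  } else {
    msg("survival: no clinical table, skipping")
  }

  counts <- list(bsp_samples = nrow(sample_df),
                 clones_passing = sum(sample_df$n_clones),
                 has_survival = !is.null(lr))
  manifest <- run_manifest(out_dir, params,
                           inputs[!vapply(inputs, is.null, logical(1))],
                           counts)
  invisible(list(samples = sample_df, group_test = gt, roc = rc,
                 youden = yd, km = km, logrank = lr, manifest = manifest))
}

#' Simulate fixtures and run both pipeline arms
#'
#' @param out_dir output directory; fixtures go to `out_dir/fixtures`,
#'   results to `out_dir/screen` and `out_dir/validation`.
#' @param cfg simulation configuration from [sim_config()].
#' @param params analysis parameters from [pipeline_params()].
#' @return invisible list with `sim`, `screen`, `validation`.
#' @export
run_demo <- function(out_dir, cfg = sim_config(), params = pipeline_params()) {
  sim <- simulate_all(cfg, file.path(out_dir, "fixtures"))
  screen <- run_screen(
    list(manifest = sim$paths$manifest, gtf = sim$paths$gtf,
         beta = sim$paths$beta, counts = sim$paths$counts,
         samples = sim$paths$samples),
    file.path(out_dir, "screen"), params)
  validation <- run_validation(
    list(bsp_ref = sim$paths$bsp_ref, bsp_dir = sim$paths$bsp_dir,
         bsp_sheet = sim$paths$bsp_sheet, clinical = sim$paths$clinical),
    file.path(out_dir, "validation"), params)
  invisible(list(sim = sim, screen = screen, validation = validation))
}
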
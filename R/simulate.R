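# Synthetic-data generators with planted ground truth.
#
# Every fixture the pipeline consumes can be generated here: a toy genome
# with lncRNA transcripts and CpG-island-bearing driver promoters, a 450K-
# style probe manifest, beta-value and count matrices with planted
# promoter hyper/hypomethylation anticorrelated with expression, BSP clone
# sequences with imperfect bisulfite conversion, and exponential survival
# times with group-dependent hazards. Each generator draws from its own
# stream, derived from the master seed by a fixed offset, so partial runs
# stay reproducible.

.stream_offsets <- c(annotation = 11L, methylation = 23L, counts = 37L,
                     bsp = 53L, survival = 71L)

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed((seed + .stream_offsets[[stream]]) %% .Machine$integer.max)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(expr)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is exercised under:
#' planted promoter delta-beta of 0.5, planted two-fold-change-squared
#' expression effects (log2fc 2), negative-binomial dispersion 0.2, 20
#' tumor vs 20 normal arrays, Beta(2,2) null methylation, BSP clone
#' methylation probabilities 0.361 (tumor) vs 0.055 (normal) with 10 clones
#' per sample over 18 tissue pairs, and a hazard ratio of 3 for the
#' high-methylation survival group.
#'
#' @param seed master seed; every generator derives its own stream from it.
#' @param n_tumor,n_normal array sample sizes per group.
#' @param n_genes,n_probes numbers of lncRNA genes and CpG probes.
#' @param frac_driver fraction of genes planted as methylation drivers
#'   (half hypermethylated/downregulated, half the mirror image).
#' @param frac_probes_in_promoter fraction of probes placed inside
#'   promoter windows.
#' @param delta_beta_planted planted promoter methylation shift.
#' @param log2fc_planted planted expression log2 fold change.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param beta_shape_null shape parameters of the null Beta distribution.
#' @param link_k linkage coefficient: driver-gene expression means are
#'   scaled by `2^(-link_k * centered promoter beta)` per sample, inducing
#'   negative methylation-expression correlation (0 disables).
#' @param hazard_ratio hazard ratio of the high- vs low-marker group.
#' @param censor_rate probability a subject is censored.
#' @param clone_meth_p named vector of per-CpG methylation probabilities
#'   for BSP clones, `c(tumor = ..., normal = ...)`.
#' @param conversion_eff bisulfite conversion efficiency for unmethylated
#'   cytosines.
#' @param n_bsp_pairs tumor/normal tissue pairs in the BSP arm.
#' @param clones_per_sample sequenced clones per BSP sample.
#' @param upstream,downstream promoter window extents in bp.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tumor = 20L, n_normal = 20L,
                       n_genes = 300L, n_probes = 2000L,
                       frac_driver = 0.1,
                       frac_probes_in_promoter = 0.3,
                       delta_beta_planted = 0.5,
                       log2fc_planted = 2,
                       nb_dispersion = 0.2,
                       beta_shape_null = c(2, 2),
                       link_k = 1,
                       hazard_ratio = 3,
                       censor_rate = 0.3,
                       clone_meth_p = c(tumor = 0.361, normal = 0.055),
                       conversion_eff = 0.99,
                       n_bsp_pairs = 18L,
                       clones_per_sample = 10L,
                       upstream = 2500L, downstream = 1000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$frac_driver >= 0, cfg$frac_driver <= 1,
            cfg$frac_probes_in_promoter >= 0, cfg$frac_probes_in_promoter <= 1,
            cfg$censor_rate >= 0, cfg$censor_rate <= 1,
            cfg$conversion_eff >= 0, cfg$conversion_eff <= 1,
            cfg$hazard_ratio > 0)
  structure(cfg, class = "sim_config")
}

rand_seq <- function(n, p_gc) {
  p <- c(A = (1 - p_gc) / 2, C = p_gc / 2, G = p_gc / 2, T = (1 - p_gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# moment-parameterized Beta draw, clipped into (0,1)
rbeta_mean <- function(n, mean, precision = 30) {
  mean <- min(max(mean, 0.02), 0.98)
  stats::rbeta(n, mean * precision, (1 - mean) * precision)
}

#' Generate the annotation fixtures: manifest, GTF and toy genome
#'
#' Lays `n_genes` 2-kb lncRNA transcripts on 3 chromosomes (alternating
#' strands and lincRNA/antisense biotypes), plants `frac_driver` of them as
#' methylation drivers, and places probes so that
#' `frac_probes_in_promoter` of them fall in promoter windows (driver
#' promoters receive a tight probe cluster near the TSS, so region calling
#' has something to find). Driver promoter cores are GC-rich, so CpG-island
#' prediction fires on them; the rest of the genome is AT-biased.
#'
#' @param cfg `sim_config`.
#' @return list with `manifest`, `transcripts`, `truth_join` (data.frames),
#'   `genome` (named character vector), `genes` (truth table with driver
#'   status and planted directions).
#' @export
gen_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stream(cfg$seed, "annotation", {
    n_genes <- cfg$n_genes
    chroms <- paste0("chr", 1:3)
    gene_chrom <- chroms[((seq_len(n_genes) - 1L) %% 3L) + 1L]
    slot <- (seq_len(n_genes) - 1L) %/% 3L
    tx_start <- 5000L + slot * 12000L
    tx_len <- 2000L
    strand <- ifelse(seq_len(n_genes) %% 2L == 1L, "+", "-")
    gene_id <- sprintf("LNC%04d", seq_len(n_genes))
    transcripts <- data.frame(
      gene_id = gene_id,
      transcript_id = paste0(gene_id, ".1"),
      gene_name = paste0("LINC-", seq_len(n_genes)),
      gene_type = ifelse(seq_len(n_genes) %% 2L == 1L, "lincRNA", "antisense"),
      chrom = gene_chrom, start = tx_start, end = tx_start + tx_len,
      strand = strand, stringsAsFactors = FALSE)

    n_driver <- round(cfg$frac_driver * n_genes)
    drivers <- sort(sample(n_genes, n_driver))
    meth_dir <- rep(NA_character_, n_genes)
    if (n_driver > 0) {
      meth_dir[drivers] <- rep_len(c("hyper", "hypo"), n_driver)
    }
    genes <- data.frame(
      gene_id = gene_id, chrom = gene_chrom, strand = strand,
      driver = seq_len(n_genes) %in% drivers,
      meth_direction = meth_dir,
      expr_direction = ifelse(is.na(meth_dir), NA,
                              ifelse(meth_dir == "hyper", "down", "up")),
      stringsAsFactors = FALSE)

    win <- promoter_windows(transcripts, cfg$upstream, cfg$downstream)
    n_in <- round(cfg$n_probes * cfg$frac_probes_in_promoter)

    probe_gene <- character(0); probe_chrom <- character(0); probe_pos <- integer(0)
    # driver promoters: a tight cluster of 5 probes near the TSS (<= 500 bp
    # gaps, so they can form a region); other in-promoter probes uniform
    cluster_size <- 5L
    for (d in drivers) {
      offs <- sort(sample(0:400, cluster_size))
      pos <- if (strand[d] == "+") win$tss[d] + offs else win$tss[d] - offs
      probe_gene <- c(probe_gene, rep(gene_id[d], cluster_size))
      probe_chrom <- c(probe_chrom, rep(gene_chrom[d], cluster_size))
      probe_pos <- c(probe_pos, as.integer(pos))
    }
    n_left <- max(n_in - length(probe_pos), 0L)
    if (n_left > 0) {
      g <- rep_len(seq_len(n_genes), n_left)
      pos <- vapply(g, function(i) {
        as.integer(sample(win$start[i]:(win$end[i] - 1L), 1L))
      }, integer(1))
      probe_gene <- c(probe_gene, gene_id[g])
      probe_chrom <- c(probe_chrom, gene_chrom[g])
      probe_pos <- c(probe_pos, pos)
    }
    # intergenic probes in the dead zone between promoter windows
    n_out <- cfg$n_probes - length(probe_pos)
    g <- rep_len(seq_len(n_genes), n_out)
    pos <- tx_start[g] + 6000L + as.integer(floor(stats::runif(n_out, 0, 3000)))
    probe_gene <- c(probe_gene, rep(NA_character_, n_out))
    probe_chrom <- c(probe_chrom, gene_chrom[g])
    probe_pos <- c(probe_pos, pos)

    ord <- order(probe_chrom, probe_pos)
    manifest <- data.frame(
      probe_id = sprintf("cg%07d", seq_along(ord)),
      chrom = probe_chrom[ord], pos = probe_pos[ord],
      strand = "+", stringsAsFactors = FALSE)
    truth_join <- data.frame(probe_id = manifest$probe_id,
                             gene_id = probe_gene[ord],
                             stringsAsFactors = FALSE)
    truth_join <- truth_join[!is.na(truth_join$gene_id), , drop = FALSE]
    truth_join <- truth_join[order(truth_join$gene_id, truth_join$probe_id), ,
                             drop = FALSE]
    rownames(truth_join) <- NULL

    # toy genome: AT-biased background, GC-rich island in driver promoters
    chrom_len <- vapply(chroms, function(ch) {
      max(tx_start[gene_chrom == ch]) + tx_len + 10000L
    }, integer(1))
    genome <- vapply(chroms, function(ch) rand_seq(chrom_len[[ch]], 0.35),
                     character(1))
    for (d in drivers) {
      ch <- gene_chrom[d]
      core <- rand_seq(600L, 0.72)
      at <- win$tss[d] - 300L
      s <- genome[[ch]]
      genome[[ch]] <- paste0(substr(s, 1, at), core,
                             substr(s, at + 601L, nchar(s)))
    }
    list(manifest = manifest, transcripts = transcripts,
         truth_join = truth_join, genome = genome, genes = genes,
         windows = win)
  })
}

#' Generate the beta-value matrix with planted promoter methylation shifts
#'
#' Null probes draw i.i.d. from `Beta(beta_shape_null)` in both groups.
#' Probes in driver promoters draw from moment-parameterized Beta
#' distributions: hypermethylated drivers have normal-mean 0.15 and tumor
#' mean shifted up by `delta_beta_planted`; hypomethylated drivers mirror
#' this around 0.85.
#'
#' @param cfg `sim_config`.
#' @param ann result of [gen_annotation()].
#' @return list with `beta` (matrix), `group` (labels), `truth_probes`
#'   (planted per-probe effects) and `truth_dmrs` (planted driver-cluster
#'   spans).
#' @export
gen_methylation <- function(cfg, ann) {
  with_stream(cfg$seed, "methylation", {
    samples <- c(sprintf("T%02d", seq_len(cfg$n_tumor)),
                 sprintf("N%02d", seq_len(cfg$n_normal)))
    group <- rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal))
    n_s <- length(samples)
    man <- ann$manifest
    beta <- matrix(stats::rbeta(nrow(man) * n_s, cfg$beta_shape_null[1],
                                cfg$beta_shape_null[2]),
                   nrow = nrow(man), ncol = n_s,
                   dimnames = list(man$probe_id, samples))
    gmap <- ann$genes
    probe_gene <- ann$truth_join$gene_id[match(man$probe_id,
                                               ann$truth_join$probe_id)]
    pdir <- gmap$meth_direction[match(probe_gene, gmap$gene_id)]
    planted <- !is.na(pdir)
    for (i in which(planted)) {
      if (pdir[i] == "hyper") {
        lo <- 0.15; hi <- 0.15 + cfg$delta_beta_planted
        beta[i, group == "normal"] <- rbeta_mean(cfg$n_normal, lo)
        beta[i, group == "tumor"] <- rbeta_mean(cfg$n_tumor, hi)
      } else {
        hi <- 0.85; lo <- 0.85 - cfg$delta_beta_planted
        beta[i, group == "normal"] <- rbeta_mean(cfg$n_normal, hi)
        beta[i, group == "tumor"] <- rbeta_mean(cfg$n_tumor, lo)
      }
    }
    truth_probes <- data.frame(
      probe_id = man$probe_id, gene_id = probe_gene,
      planted = planted,
      planted_direction = pdir,
      planted_delta_beta = ifelse(planted,
                                  ifelse(pdir == "hyper", 1, -1) *
                                    cfg$delta_beta_planted, 0),
      stringsAsFactors = FALSE)
    # planted driver probe clusters = expected regions
    td <- truth_probes[truth_probes$planted, , drop = FALSE]
    spans <- lapply(split(td$probe_id, td$gene_id), function(pids) {
      rows <- man[man$probe_id %in% pids, , drop = FALSE]
      data.frame(chrom = rows$chrom[1], start = min(rows$pos),
                 end = max(rows$pos) + 1L, n_probes = nrow(rows),
                 probe_ids = paste(sort(rows$probe_id), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    truth_dmrs <- if (length(spans)) {
      cbind(gene_id = names(spans), do.call(rbind, spans))
    } else {
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), n_probes = integer(),
                 probe_ids = character())
    }
    rownames(truth_dmrs) <- NULL
    list(beta = beta, group = group, truth_probes = truth_probes,
         truth_dmrs = truth_dmrs)
  })
}

#' Generate the count matrix with planted expression changes
#'
#' Gene means follow `baseline * 2^(effect)`, with driver genes' tumor
#' effect equal to `-log2fc_planted` when hypermethylated and
#' `+log2fc_planted` when hypomethylated. In linkage mode (`link_k > 0`,
#' requires `meth`) each driver gene's per-sample mean is further scaled by
#' `2^(-link_k * centered mean promoter beta)`, inducing the negative
#' methylation-expression correlation the integration stage looks for.
#' Counts are negative-binomial with dispersion `nb_dispersion`.
#'
#' @param cfg `sim_config`.
#' @param ann result of [gen_annotation()].
#' @param meth optional result of [gen_methylation()] for linkage mode.
#' @return list with `counts` (integer matrix), `group`, `truth_genes`.
#' @export
gen_counts <- function(cfg, ann, meth = NULL) {
  with_stream(cfg$seed, "counts", {
    samples <- c(sprintf("T%02d", seq_len(cfg$n_tumor)),
                 sprintf("N%02d", seq_len(cfg$n_normal)))
    group <- rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal))
    genes <- ann$genes
    n_g <- nrow(genes); n_s <- length(samples)
    baseline <- stats::rlnorm(n_g, meanlog = log(300), sdlog = 1)
    eff <- ifelse(is.na(genes$expr_direction), 0,
                  ifelse(genes$expr_direction == "up", 1, -1)) *
           cfg$log2fc_planted
    mu <- matrix(baseline, n_g, n_s)
    mu[, group == "tumor"] <- mu[, group == "tumor"] *
      2^(matrix(eff, n_g, sum(group == "tumor")))
    if (!is.null(meth) && cfg$link_k > 0) {
      tj <- ann$truth_join
      for (i in which(genes$driver)) {
        pids <- tj$probe_id[tj$gene_id == genes$gene_id[i]]
        pids <- intersect(pids, rownames(meth$beta))
        if (!length(pids)) next
        pb <- colMeans(meth$beta[pids, , drop = FALSE])
        mu[i, ] <- mu[i, ] * 2^(-cfg$link_k * (pb - mean(pb)))
      }
    }
    size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
    counts <- matrix(
      if (is.finite(size)) stats::rnbinom(n_g * n_s, mu = mu, size = size)
      else stats::rpois(n_g * n_s, lambda = mu),
      n_g, n_s, dimnames = list(genes$gene_id, samples))
    truth_genes <- data.frame(
      gene_id = genes$gene_id, driver = genes$driver,
      meth_direction = genes$meth_direction,
      expr_direction = genes$expr_direction,
      planted_log2fc = eff, stringsAsFactors = FALSE)
    list(counts = counts, group = group, truth_genes = truth_genes)
  })
}

#' Generate BSP reference amplicon and clone sequences
#'
#' Builds a reference amplicon with `n_cpg` CpG sites in a GC-rich context,
#' then simulates `clones_per_sample` clones for each of `n_bsp_pairs`
#' tumor/normal tissue pairs. Per clone, each CpG is methylated with its
#' sample's methylation probability (drawn per sample from a
#' mean-preserving Beta around the group's `clone_meth_p`, precision 10,
#' emulating inter-patient variability); unmethylated CpG cytosines and
#' all non-CpG cytosines convert C-to-T with probability `conversion_eff`.
#'
#' @param cfg `sim_config`.
#' @param n_cpg CpG sites in the amplicon (default 20).
#' @return list with `ref` (`bsp_amplicon`), `clones` (named list of named
#'   character vectors, one per sample), `sheet` (sample, group,
#'   true per-sample methylation probability).
#' @export
gen_bsp <- function(cfg, n_cpg = 20L) {
  with_stream(cfg$seed, "bsp", {
    blocks <- vapply(seq_len(n_cpg), function(i) {
      paste0(rand_seq(8L, 0.45), "CG")
    }, character(1))
    ref_seq <- paste0(rand_seq(15L, 0.45), paste(blocks, collapse = ""),
                      rand_seq(15L, 0.45))
    # strip accidental extra CpGs so cpg count is controlled by design
    ref_seq <- gsub("CG", "CA", ref_seq)
    ref_seq <- sub("^(.{0})", "", ref_seq)
    for (i in seq_len(n_cpg)) {
      at <- 15L + (i - 1L) * 10L + 9L   # position of each planted CG
      substr(ref_seq, at, at + 1L) <- "CG"
    }
    ref <- amplicon("amplicon1", ref_seq)
    samples <- c(sprintf("BT%02d", seq_len(cfg$n_bsp_pairs)),
                 sprintf("BN%02d", seq_len(cfg$n_bsp_pairs)))
    groups <- rep(c("tumor", "normal"), each = cfg$n_bsp_pairs)
    # per-sample methylation probability around the group mean
    # (mean-preserving Beta noise, precision 10)
    meth_p <- vapply(cfg$clone_meth_p[groups],
                     function(p) rbeta_mean(1L, p, precision = 10),
                     numeric(1))
    clones <- lapply(seq_along(samples), function(s) {
      out <- vapply(seq_len(cfg$clones_per_sample), function(k) {
        ch <- strsplit(ref$seq, "")[[1]]
        cpos <- ref$cpg_positions + 1L
        meth <- stats::runif(length(cpos)) < meth_p[s]
        conv_cpg <- !meth & (stats::runif(length(cpos)) < cfg$conversion_eff)
        ch[cpos[conv_cpg]] <- "T"
        non_cpg_c <- setdiff(which(ch == "C"), cpos)
        conv <- stats::runif(length(non_cpg_c)) < cfg$conversion_eff
        ch[non_cpg_c[conv]] <- "T"
        paste(ch, collapse = "")
      }, character(1))
      names(out) <- sprintf("%s_clone%02d", samples[s],
                            seq_len(cfg$clones_per_sample))
      out
    })
    names(clones) <- samples
    sheet <- data.frame(sample_id = samples, group = groups,
                        true_meth_p = unname(meth_p),
                        stringsAsFactors = FALSE)
    list(ref = ref, clones = clones, sheet = sheet)
  })
}

#' Generate a clinical survival table
#'
#' Event times are exponential with hazard `log(2)/24` per month for the
#' low-marker group and `hazard_ratio` times that for the high group
#' (split at the marker median). Each subject is independently censored
#' with probability `censor_rate`, at a uniform fraction of its event time.
#'
#' @param cfg `sim_config`.
#' @param markers data.frame with columns `sample_id` and `marker` (e.g.
#'   BSP methylation rates).
#' @return data.frame with columns `sample_id`, `time` (months), `event`,
#'   `marker`.
#' @export
gen_survival <- function(cfg, markers) {
  with_stream(cfg$seed, "survival", {
    n <- nrow(markers)
    high <- markers$marker > stats::median(markers$marker)
    h0 <- log(2) / 24
    rate <- h0 * ifelse(high, cfg$hazard_ratio, 1)
    t_event <- stats::rexp(n, rate)
    cens <- stats::runif(n) < cfg$censor_rate
    time <- ifelse(cens, t_event * stats::runif(n), t_event)
    data.frame(sample_id = markers$sample_id,
               time = round(pmax(time, 0.01), 3),
               event = as.integer(!cens),
               marker = markers$marker,
               stringsAsFactors = FALSE)
  })
}

write_gtf <- function(transcripts, path) {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_type "%s"; gene_name "%s";',
    transcripts$gene_id, transcripts$transcript_id,
    transcripts$gene_type, transcripts$gene_name)
  lines <- c(
    "##description: synthetic lncRNA annotation",
    sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            transcripts$chrom, transcripts$start + 1L, transcripts$end,
            transcripts$strand, attrs))
  writeLines(lines, path)
  invisible(path)
}

#' Generate and write every fixture for a full pipeline run
#'
#' @param cfg `sim_config`.
#' @param out_dir output directory (created if absent).
#' @return invisible list of the generated objects plus `paths` to every
#'   written file.
#' @export
simulate_all <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sub <- function(...) {
    d <- file.path(out_dir, ...)
    dir.create(dirname(d), showWarnings = FALSE, recursive = TRUE)
    d
  }
  ann <- gen_annotation(cfg)
  meth <- gen_methylation(cfg, ann)
  expr <- gen_counts(cfg, ann, meth)
  bsp <- gen_bsp(cfg)
  clin <- gen_survival(cfg, data.frame(sample_id = bsp$sheet$sample_id,
                                       marker = bsp$sheet$true_meth_p))

  paths <- list(
    manifest = sub("annotation", "manifest.tsv"),
    gtf = sub("annotation", "transcripts.gtf"),
    genome = sub("annotation", "genome.fa"),
    truth_join = sub("truth", "join.tsv"),
    beta = sub("methylation", "beta.tsv"),
    counts = sub("expression", "counts.tsv"),
    samples = sub("samples.tsv"),
    bsp_ref = sub("bsp", "reference.fa"),
    bsp_dir = sub("bsp", "clones"),
    bsp_sheet = sub("bsp", "sheet.tsv"),
    clinical = sub("clinical.tsv"),
    truth_genes = sub("truth", "genes.tsv"),
    truth_probes = sub("truth", "probes.tsv"),
    truth_dmrs = sub("truth", "dmrs.tsv"))

  write_tsv(ann$manifest, paths$manifest)
  write_gtf(ann$transcripts, paths$gtf)
  write_fasta(ann$genome, paths$genome)
  write_tsv(ann$truth_join, paths$truth_join)
  write_tsv(data.frame(probe_id = rownames(meth$beta), meth$beta,
                       check.names = FALSE), paths$beta)
  write_tsv(data.frame(gene_id = rownames(expr$counts), expr$counts,
                       check.names = FALSE), paths$counts)
  write_tsv(data.frame(sample_id = colnames(meth$beta), group = meth$group),
            paths$samples)
  write_fasta(stats::setNames(bsp$ref$seq, bsp$ref$name), paths$bsp_ref)
  dir.create(paths$bsp_dir, showWarnings = FALSE)
  for (s in names(bsp$clones)) {
    write_fasta(bsp$clones[[s]], file.path(paths$bsp_dir, paste0(s, ".fa")))
  }
  write_tsv(bsp$sheet, paths$bsp_sheet)
  write_tsv(clin, paths$clinical)
  write_tsv(expr$truth_genes, paths$truth_genes)
  write_tsv(meth$truth_probes, paths$truth_probes)
  write_tsv(meth$truth_dmrs, paths$truth_dmrs)

  invisible(list(cfg = cfg, ann = ann, meth = meth, expr = expr,
                 bsp = bsp, clinical = clin, paths = paths))
}
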
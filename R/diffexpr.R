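# Differential lncRNA expression between tumor and normal samples.
#
# The built-in engine normalizes raw counts to CPM and applies a two-sided
# Mann-Whitney test per gene with Benjamini-Hochberg control. Externally
# produced differential-expression tables (e.g. from count-model packages)
# can be imported and intersected with the built-in results through
# consensus_de(), which treats every table identically.

#' Counts-per-million normalization with pseudocount
#'
#' `cpm[g,s] = (counts[g,s] + pc) / (lib_size[s] + 2 * pc * n_genes) * 1e6`.
#' The pseudocount keeps values strictly positive so log fold changes are
#' always defined; its contribution to the denominator keeps column sums at
#' one million.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param pseudocount added to every count (default 0.5).
#' @return numeric matrix of the same dimensions.
#' @export
cpm_normalize <- function(counts, pseudocount = 0.5) {
  if (!is.matrix(counts)) stop2("counts must be a matrix")
  if (any(counts < 0)) stop2("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop2("sample(s) with zero total count: %s",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  denom <- lib + 2 * pseudocount * nrow(counts)
  sweep(counts + pseudocount, 2, denom, "/") * 1e6
}

#' Rank-test differential expression screen
#'
#' Per gene: a two-sided Mann-Whitney U test on CPM values between tumor and
#' normal samples (exact null when the combined size is at most 12 and there
#' are no ties, otherwise normal approximation with tie correction), with
#' Benjamini-Hochberg adjustment across all genes. The log2 fold change is
#' the log2 ratio of group mean CPMs (tumor over normal). A gene is called
#' `up` when `fdr < alpha` and `log2fc >= log2(fc_min)`, `down` when
#' `fdr < alpha` and `log2fc <= -log2(fc_min)`, `ns` otherwise.
#'
#' @param counts genes x samples integer matrix with row/col names.
#' @param group per-sample labels, `"tumor"` or `"normal"`.
#' @param alpha FDR threshold (default 0.05).
#' @param fc_min minimum fold change on the natural scale (default 2).
#' @param pseudocount passed to [cpm_normalize()].
#' @return data.frame with columns `gene_id`, `log2fc`, `p`, `fdr`,
#'   `direction`.
#' @export
rank_test_de <- function(counts, group, alpha = 0.05, fc_min = 2,
                         pseudocount = 0.5) {
  group <- check_group_matrix(counts, group, "counts")
  if (sum(group == "tumor") < 2L || sum(group == "normal") < 2L) {
    stop2("at least 2 samples per group are required")
  }
  cpm <- cpm_normalize(counts, pseudocount)
  tum <- group == "tumor"
  p <- vapply(seq_len(nrow(cpm)),
              function(i) mw_test(cpm[i, tum], cpm[i, !tum])$p,
              numeric(1))
  log2fc <- log2(rowMeans(cpm[, tum, drop = FALSE]) /
                 rowMeans(cpm[, !tum, drop = FALSE]))
  const <- apply(cpm, 1, function(v) length(unique(v)) == 1L)
  log2fc[const] <- 0
  fdr <- bh_adjust(p)
  direction <- rep("ns", nrow(cpm))
  direction[fdr < alpha & log2fc >= log2(fc_min)] <- "up"
  direction[fdr < alpha & log2fc <= -log2(fc_min)] <- "down"
  data.frame(gene_id = rownames(counts), log2fc = unname(log2fc),
             p = p, fdr = fdr, direction = direction,
             stringsAsFactors = FALSE)
}

#' Import an externally produced differential-expression table
#'
#' Expects a TSV with columns `gene_id`, `log2fc`, `p`, `fdr` (extra columns
#' are ignored) and recomputes the `direction` call at the given thresholds
#' so imported and built-in tables are comparable.
#'
#' @param path TSV file.
#' @param alpha,fc_min thresholds used for the direction call.
#' @return data.frame in the same shape as [rank_test_de()] output.
#' @export
read_de_table <- function(path, alpha = 0.05, fc_min = 2) {
  df <- read_tsv_checked(path, required = c("gene_id", "log2fc", "p", "fdr"))
  direction <- rep("ns", nrow(df))
  direction[df$fdr < alpha & df$log2fc >= log2(fc_min)] <- "up"
  direction[df$fdr < alpha & df$log2fc <= -log2(fc_min)] <- "down"
  data.frame(gene_id = as.character(df$gene_id), log2fc = df$log2fc,
             p = df$p, fdr = df$fdr, direction = direction,
             stringsAsFactors = FALSE)
}

#' Consensus intersection of several differential-expression screens
#'
#' A gene is retained only if every method calls it significant
#' (`fdr < alpha` and `|log2fc| >= log2(fc_min)`) and — unless
#' `require_direction = FALSE` — all methods agree on the direction. Genes
#' with conflicting directions are silently dropped.
#'
#' @param results list of data.frames shaped like [rank_test_de()] output,
#'   all covering the same gene universe.
#' @param alpha,fc_min thresholds re-applied uniformly to every table.
#' @param require_direction drop genes whose direction differs across
#'   methods (default TRUE).
#' @return data.frame with columns `gene_id`, `direction`, sorted by gene_id.
#' @export
consensus_de <- function(results, alpha = 0.05, fc_min = 2,
                         require_direction = TRUE) {
  stopifnot(is.list(results), length(results) >= 1L)
  universe <- sort(results[[1]]$gene_id)
  for (r in results) {
    if (!setequal(r$gene_id, universe)) {
      stop2("all methods must cover the same gene universe")
    }
  }
  sig <- lapply(results, function(r) {
    keep <- r$fdr < alpha & abs(r$log2fc) >= log2(fc_min)
    data.frame(gene_id = r$gene_id[keep],
               direction = ifelse(r$log2fc[keep] >= 0, "up", "down"),
               stringsAsFactors = FALSE)
  })
  ids <- Reduce(intersect, lapply(sig, `[[`, "gene_id"))
  if (require_direction && length(ids)) {
    dirs <- sapply(ids, function(g) {
      d <- vapply(sig, function(s) s$direction[s$gene_id == g], character(1))
      if (length(unique(d)) == 1L) d[1] else NA_character_
    })
    keep <- !is.na(dirs)
    out <- data.frame(gene_id = ids[keep], direction = unname(dirs[keep]),
                      stringsAsFactors = FALSE)
  } else {
    d1 <- sig[[1]]
    out <- d1[d1$gene_id %in% ids, , drop = FALSE]
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
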
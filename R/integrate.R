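# Integration of the methylation and expression screens into
# methylation-driven (CpG, lncRNA) pairs.

#' Call methylation-driven lncRNA pairs
#'
#' A (probe, gene) pair from the promoter join is emitted when the probe is
#' differentially methylated (direction `hyper`/`hypo`) AND the gene is
#' differentially expressed (direction `up`/`down`). With
#' `require_concordance = TRUE` only the biologically expected combinations
#' (hypermethylated + downregulated, hypomethylated + upregulated) are kept.
#' Join entries whose ids are absent from the screens count as
#' non-significant; their number is attached as attribute `"n_unmatched"`.
#'
#' @param dm data.frame from [probe_dm()].
#' @param de data.frame from [rank_test_de()] (or [read_de_table()]).
#' @param join data.frame of (`probe_id`, `gene_id`) from
#'   [join_probes_to_promoters()].
#' @param require_concordance keep only hyper+down / hypo+up pairs
#'   (default FALSE).
#' @return data.frame with columns `probe_id`, `gene_id`, `delta_beta`,
#'   `log2fc`, `meth_direction`, `expr_direction`, `concordant`, sorted by
#'   (gene_id, probe_id).
#' @export
call_pairs <- function(dm, de, join, require_concordance = FALSE) {
  dm_sig <- dm[dm$direction %in% c("hyper", "hypo"), , drop = FALSE]
  de_sig <- de[de$direction %in% c("up", "down"), , drop = FALSE]
  n_unmatched <- sum(!(join$probe_id %in% dm$probe_id) |
                     !(join$gene_id %in% de$gene_id))
  keep <- join$probe_id %in% dm_sig$probe_id &
          join$gene_id %in% de_sig$gene_id
  out <- join[keep, c("probe_id", "gene_id"), drop = FALSE]
  mi <- match(out$probe_id, dm_sig$probe_id)
  gi <- match(out$gene_id, de_sig$gene_id)
  out$delta_beta <- dm_sig$delta_beta[mi]
  out$log2fc <- de_sig$log2fc[gi]
  out$meth_direction <- dm_sig$direction[mi]
  out$expr_direction <- de_sig$direction[gi]
  out$concordant <- (out$meth_direction == "hyper" & out$expr_direction == "down") |
                    (out$meth_direction == "hypo" & out$expr_direction == "up")
  if (require_concordance) out <- out[out$concordant, , drop = FALSE]
  out <- out[order(out$gene_id, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Spearman correlation between promoter methylation and expression
#'
#' Spearman rank correlation with average ranks for ties, over samples with
#' both values present. The p-value comes from the exact permutation
#' distribution when at most 8 complete pairs are available (and there are
#' no ties), otherwise from the t approximation. Fewer than 3 complete
#' pairs, or a constant vector, yield missing values with a `reason`.
#'
#' @param beta_row numeric vector of beta values (one probe across samples).
#' @param expr_row numeric vector of expression values, same sample order.
#' @return list with `rho`, `p`, `n` (complete pairs) and `reason`
#'   (`NA` when the correlation is defined).
#' @export
spearman_pair <- function(beta_row, expr_row) {
  stopifnot(length(beta_row) == length(expr_row))
  ok <- !is.na(beta_row) & !is.na(expr_row)
  n <- sum(ok)
  if (n < 3L) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                reason = "fewer than 3 complete pairs"))
  }
  x <- beta_row[ok]; y <- expr_row[ok]
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                reason = "constant vector"))
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 8L)
  )
  list(rho = unname(ht$estimate), p = ht$p.value, n = n, reason = NA_character_)
}

#' Annotate pairs with methylation-expression correlation
#'
#' @param pairs data.frame from [call_pairs()].
#' @param beta probes x samples beta matrix.
#' @param expr genes x samples expression matrix (any monotone scale; CPM
#'   or FPKM both work since the correlation is rank-based). Columns must
#'   match `beta`'s sample order.
#' @return `pairs` with added columns `rho`, `rho_p`, `rho_n`.
#' @export
correlate_pairs <- function(pairs, beta, expr) {
  if (!identical(colnames(beta), colnames(expr))) {
    stop2("beta and expr must share the same sample columns")
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs$probe_id[i]; g <- pairs$gene_id[i]
    if (!(p %in% rownames(beta)) || !(g %in% rownames(expr))) {
      return(list(rho = NA_real_, p = NA_real_, n = 0L))
    }
    spearman_pair(beta[p, ], expr[g, ])
  })
  pairs$rho <- vapply(res, `[[`, numeric(1), "rho")
  pairs$rho_p <- vapply(res, `[[`, numeric(1), "p")
  pairs$rho_n <- vapply(res, function(r) as.integer(r$n), integer(1))
  pairs
}

#' Rank methylation-driven genes by promoter delta-beta
#'
#' Each gene is represented by its maximum-|delta-beta| probe; genes are
#' then ranked by |delta-beta| descending within each methylation
#' direction, ties broken by gene_id (lexicographic).
#'
#' @param pairs data.frame from [call_pairs()].
#' @param top_k number of genes to return per direction.
#' @return list with data.frames `hyper` and `hypo` (columns `gene_id`,
#'   `probe_id`, `delta_beta`, `log2fc`).
#' @export
rank_pairs <- function(pairs, top_k = 5L) {
  per_dir <- function(dir) {
    sub <- pairs[pairs$meth_direction == dir, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(gene_id = character(), probe_id = character(),
                        delta_beta = numeric(), log2fc = numeric(),
                        stringsAsFactors = FALSE))
    }
    # per-gene representative probe = max |delta_beta|, probe_id tie-break
    sub <- sub[order(sub$gene_id, -abs(sub$delta_beta), sub$probe_id), ,
               drop = FALSE]
    sub <- sub[!duplicated(sub$gene_id), , drop = FALSE]
    sub <- sub[order(-abs(sub$delta_beta), sub$gene_id), , drop = FALSE]
    head(sub[, c("gene_id", "probe_id", "delta_beta", "log2fc")], top_k)
  }
  list(hyper = per_dir("hyper"), hypo = per_dir("hypo"))
}
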
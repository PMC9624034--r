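# Per-probe differential methylation and bump-hunting DMR detection.
#
# Effect size is delta-beta (mean tumor beta minus mean normal beta).
# Region calling follows the bump-hunter scheme: probes are clustered by
# genomic proximity, candidate regions are maximal runs of consecutive
# probes whose |delta-beta| exceeds a cutoff with a common sign, and
# region-level significance comes from permuting sample group labels and
# comparing each candidate's area (sum of |delta-beta|) against the
# permutation maxima. No curve smoothing is applied.

delta_beta_vec <- function(beta, tum) {
  rowMeans(beta[, tum, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, !tum, drop = FALSE], na.rm = TRUE)
}

#' Per-probe differential methylation screen
#'
#' Per probe: delta-beta over non-missing entries, a two-sided Mann-Whitney
#' test, and Benjamini-Hochberg adjustment across all tested probes. Probes
#' with fewer than 2 non-missing values in either group are skipped; their
#' ids are attached as attribute `"skipped"`.
#'
#' @param beta probes x samples matrix of methylation fractions in `[0,1]`,
#'   NAs allowed.
#' @param group per-sample labels, `"tumor"` or `"normal"`.
#' @param alpha FDR threshold for the direction call (default 0.05).
#' @return data.frame with columns `probe_id`, `delta_beta`, `p`, `fdr`,
#'   `direction` (`hyper`/`hypo`/`ns`); attribute `skipped` lists excluded
#'   probe ids.
#' @export
probe_dm <- function(beta, group, alpha = 0.05) {
  group <- check_group_matrix(beta, group, "beta")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop2("beta values must lie in [0,1]")
  tum <- group == "tumor"
  n_t <- rowSums(!is.na(beta[, tum, drop = FALSE]))
  n_n <- rowSums(!is.na(beta[, !tum, drop = FALSE]))
  ok <- n_t >= 2L & n_n >= 2L
  skipped <- rownames(beta)[!ok]
  b <- beta[ok, , drop = FALSE]
  db <- delta_beta_vec(b, tum)
  p <- vapply(seq_len(nrow(b)),
              function(i) mw_test(b[i, tum], b[i, !tum])$p,
              numeric(1))
  fdr <- bh_adjust(p)
  direction <- rep("ns", nrow(b))
  direction[fdr < alpha & db > 0] <- "hyper"
  direction[fdr < alpha & db < 0] <- "hypo"
  out <- data.frame(probe_id = rownames(b), delta_beta = unname(db),
                    p = p, fdr = fdr, direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

# Maximal runs of consecutive probes (already in genomic order, within one
# proximity cluster) with |delta| >= cutoff and a common sign.
dmr_candidates <- function(delta, pos, probe_ids, chrom, cutoff, min_probes) {
  sgn <- sign(delta) * (abs(delta) >= cutoff & !is.na(delta))
  out <- list()
  i <- 1L
  n <- length(delta)
  while (i <= n) {
    if (sgn[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j < n && sgn[j + 1L] == sgn[i]) j <- j + 1L
    if (j - i + 1L >= min_probes) {
      idx <- i:j
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = min(pos[idx]),
        end = max(pos[idx]) + 1L,
        probe_ids = paste(probe_ids[idx], collapse = ","),
        n_probes = length(idx),
        mean_delta_beta = mean(delta[idx]),
        area = sum(abs(delta[idx])),
        stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  out
}

cluster_and_candidates <- function(delta, probes, cutoff, min_probes, max_gap) {
  out <- list()
  for (chr in unique(probes$chrom)) {
    sel <- which(probes$chrom == chr)
    sel <- sel[order(probes$pos[sel])]
    pos <- probes$pos[sel]
    cl <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
    for (k in unique(cl)) {
      s <- sel[cl == k]  # already in position order
      out <- c(out, dmr_candidates(delta[probes$probe_id[s]],
                                   probes$pos[s], probes$probe_id[s],
                                   chr, cutoff, min_probes))
    }
  }
  out
}

#' Detect differentially methylated regions by permutation bump hunting
#'
#' Probes are clustered per chromosome with inter-probe gaps of at most
#' `max_gap` bp. Within a cluster, a candidate DMR is a maximal run of
#' consecutive probes with `|delta_beta| >= cutoff` and identical sign;
#' candidates with fewer than `min_probes` probes are discarded. The null
#' distribution is built by permuting the sample group labels `resamples`
#' times (missing betas are imputed as the group mean for the permutation
#' rounds only, keeping the null exchangeable) and recording the maximum
#' candidate area per permutation. The empirical p-value uses add-one
#' smoothing: `p = (1 + #{null max area >= observed area}) / (resamples + 1)`.
#'
#' @param beta probes x samples beta matrix (rownames = probe ids).
#' @param group per-sample `"tumor"`/`"normal"` labels.
#' @param probes manifest data.frame ([read_manifest()]) covering the rows
#'   of `beta`.
#' @param cutoff minimum `|delta_beta|` for a probe to enter a candidate
#'   (default 0.2).
#' @param min_probes minimum probes per region (default 2).
#' @param resamples number of label permutations (default 100).
#' @param max_gap maximum intra-cluster probe gap in bp (default 500).
#' @param seed integer seed for the permutation stream.
#' @return data.frame with columns `chrom`, `start`, `end`, `probe_ids`
#'   (comma-separated), `n_probes`, `mean_delta_beta`, `area`,
#'   `p_empirical`, sorted by p then area descending; zero rows when no
#'   candidate exists.
#' @export
find_dmrs <- function(beta, group, probes, cutoff = 0.2, min_probes = 2L,
                      resamples = 100L, max_gap = 500L, seed = 1L) {
  group <- check_group_matrix(beta, group, "beta")
  if (cutoff <= 0 || cutoff >= 1) stop2("cutoff must lie in (0,1)")
  if (resamples < 1L) stop2("resamples must be >= 1")
  probes <- probes[probes$probe_id %in% rownames(beta), , drop = FALSE]
  if (anyDuplicated(probes$probe_id)) stop2("duplicated probe ids in manifest")
  beta <- beta[probes$probe_id, , drop = FALSE]
  tum <- group == "tumor"

  delta <- delta_beta_vec(beta, tum)
  cand <- cluster_and_candidates(delta, probes, cutoff, min_probes, max_gap)
  if (!length(cand)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), probe_ids = character(),
                      n_probes = integer(), mean_delta_beta = numeric(),
                      area = numeric(), p_empirical = numeric()))
  }
  obs <- do.call(rbind, cand)

  # group-mean imputation for the permutation rounds only
  bimp <- beta
  for (g in list(tum, !tum)) {
    sub <- beta[, g, drop = FALSE]
    gm <- rowMeans(sub, na.rm = TRUE)
    idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(idx)) sub[idx] <- gm[idx[, 1]]
    bimp[, g] <- sub
  }
  n_tum <- sum(tum)
  null_max <- numeric(resamples)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (b in seq_len(resamples)) {
    perm <- sample(ncol(bimp))
    ptum <- logical(ncol(bimp))
    ptum[perm[seq_len(n_tum)]] <- TRUE
    pdelta <- delta_beta_vec(bimp, ptum)
    pc <- cluster_and_candidates(pdelta, probes, cutoff, min_probes, max_gap)
    null_max[b] <- if (length(pc)) max(vapply(pc, `[[`, numeric(1), "area")) else 0
  }
  obs$p_empirical <- vapply(obs$area, function(a) {
    (1 + sum(null_max >= a)) / (resamples + 1)
  }, numeric(1))
  obs <- obs[order(obs$p_empirical, -obs$area), , drop = FALSE]
  rownames(obs) <- NULL
  obs
}
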
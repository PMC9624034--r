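# Independent brute-force oracles used to check the implementation paths.

# all-pairs containment scan for the probe/promoter join
oracle_join <- function(probes, windows) {
  out <- list()
  for (i in seq_len(nrow(probes))) {
    for (j in seq_len(nrow(windows))) {
      if (probes$chrom[i] == windows$chrom[j] &&
          probes$pos[i] >= windows$start[j] &&
          probes$pos[i] < windows$end[j]) {
        out[[length(out) + 1L]] <- data.frame(
          probe_id = probes$probe_id[i], gene_id = windows$gene_id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(probe_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, out))
  out <- out[order(out$gene_id, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pairwise U-statistic AUC with 0.5 credit for ties
oracle_auc <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# exhaustive Youden scan over every threshold between -Inf and +Inf
oracle_youden <- function(values, labels) {
  labels <- as.logical(labels)
  sv <- sort(unique(values))
  thr <- c(-Inf, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  best <- NULL
  for (t in thr) {
    sens <- sum(values >= t & labels) / sum(labels)
    spec <- sum(values < t & !labels) / sum(!labels)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (sens > best$sens + 1e-12 ||
          (abs(sens - best$sens) <= 1e-12 && t < best$cutoff)))) {
      best <- list(cutoff = t, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# exact two-sided Mann-Whitney p by enumerating every label assignment
oracle_mw_exact_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)])
  e <- n1 * (length(v) + 1) / 2
  combos <- utils::combn(length(v), n1)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(stats - e) >= abs(obs - e) - 1e-9)
}

# two-sided Spearman p by enumerating every permutation of y
oracle_spearman <- function(x, y) {
  rho_of <- function(a, b) stats::cor(rank(a), rank(b))
  obs <- rho_of(x, y)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  rs <- vapply(perms(y), function(p) rho_of(x, p), numeric(1))
  list(rho = obs, p = mean(abs(rs) >= abs(obs) - 1e-9))
}

# direct sliding-window island scan (no cumulative sums)
oracle_islands <- function(seq, min_len = 200L, min_gc = 0.5, min_oe = 0.6) {
  n <- nchar(seq)
  if (n < min_len) return(integer(0))
  pass <- logical(n - min_len + 1L)
  for (s in seq_len(n - min_len + 1L)) {
    w <- substr(seq, s, s + min_len - 1L)
    ch <- strsplit(w, "")[[1]]
    nc <- sum(ch == "C"); ng <- sum(ch == "G")
    ncg <- sum(ch[-min_len] == "C" & ch[-1] == "G")
    gc <- (nc + ng) / min_len
    oe <- if (nc > 0 && ng > 0) ncg * min_len / (nc * ng) else 0
    pass[s] <- gc >= min_gc && oe >= min_oe
  }
  pass
}

# hand hypergeometric tally for the two-group log-rank statistic
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# brute-force maximal qualifying runs for the DMR candidate scan
oracle_dmr_runs <- function(delta, pos, cutoff, min_probes, max_gap) {
  qual <- abs(delta) >= cutoff
  sgn <- sign(delta)
  runs <- list()
  i <- 1L
  while (i <= length(delta)) {
    if (!qual[i]) { i <- i + 1L; next }
    j <- i
    while (j < length(delta) && qual[j + 1L] && sgn[j + 1L] == sgn[i] &&
           pos[j + 1L] - pos[j] <= max_gap) j <- j + 1L
    if (j - i + 1L >= min_probes) runs[[length(runs) + 1L]] <- i:j
    i <- j + 1L
  }
  runs
}

sim_tmpdir <- function() {
  d <- tempfile("lncmeth_test_")
  dir.create(d)
  d
}
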
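# CpG-island prediction by the Gardiner-Garden & Frommer criteria.

#' Predict CpG islands in a DNA sequence
#'
#' Slides a `min_len`-bp window one base at a time and marks windows with GC
#' fraction >= `min_gc` and observed/expected CpG ratio >= `min_oe`, where
#' O/E = (#CG dinucleotides * L) / (#C * #G). Overlapping or adjacent passing
#' windows are merged into maximal islands, whose merged statistics are then
#' revalidated against the same thresholds. `N` bases count toward window
#' length but not toward base or dinucleotide counts.
#'
#' @param seq a single DNA string over A/C/G/T/N (case-insensitive).
#' @param min_len minimum island (and window) length in bp.
#' @param min_gc minimum GC fraction.
#' @param min_oe minimum observed/expected CpG ratio.
#' @return data.frame with columns `start`, `end` (0-based half-open,
#'   relative to `seq`), `gc_fraction`, `obs_exp_cpg`; zero rows when no
#'   island is found or `seq` is shorter than `min_len`.
#' @export
find_cpg_islands <- function(seq, min_len = 200L, min_gc = 0.5, min_oe = 0.6) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(),
                      gc_fraction = numeric(), obs_exp_cpg = numeric())
  if (n < min_len) return(empty)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("A", "C", "G", "T", "N"))) {
    stop2("sequence contains characters outside A/C/G/T/N")
  }
  is_c <- as.integer(ch == "C")
  is_g <- as.integer(ch == "G")
  is_cg <- as.integer(ch[-n] == "C" & ch[-1] == "G")  # dinucleotide starts
  cum_c <- c(0L, cumsum(is_c))
  cum_g <- c(0L, cumsum(is_g))
  cum_cg <- c(0L, cumsum(is_cg))

  win_stats <- function(s, e) {   # 0-based half-open span
    L <- e - s
    nc <- cum_c[e + 1L] - cum_c[s + 1L]
    ng <- cum_g[e + 1L] - cum_g[s + 1L]
    # CG dinucleotides fully inside the span
    ncg <- if (L < 2L) 0L else cum_cg[e] - cum_cg[s + 1L]
    gc <- (nc + ng) / L
    oe <- if (nc > 0L && ng > 0L) (ncg * L) / (nc * ng) else 0
    c(gc = gc, oe = oe)
  }

  starts <- 0:(n - min_len)
  nc_w <- cum_c[starts + min_len + 1L] - cum_c[starts + 1L]
  ng_w <- cum_g[starts + min_len + 1L] - cum_g[starts + 1L]
  ncg_w <- cum_cg[starts + min_len] - cum_cg[starts + 1L]
  gc_w <- (nc_w + ng_w) / min_len
  oe_w <- ifelse(nc_w > 0L & ng_w > 0L, (ncg_w * min_len) / (nc_w * ng_w), 0)
  pass <- gc_w >= min_gc & oe_w >= min_oe
  if (!any(pass)) return(empty)

  # merge passing windows whose intervals overlap or touch (start gap <=
  # window length) into maximal islands
  ps <- starts[pass]
  grp <- cumsum(c(1L, as.integer(diff(ps) > min_len)))
  out <- list()
  for (k in unique(grp)) {
    g <- ps[grp == k]
    s0 <- g[1]
    e0 <- g[length(g)] + min_len
    st <- win_stats(s0, e0)
    if ((e0 - s0) >= min_len && st["gc"] >= min_gc && st["oe"] >= min_oe) {
      out[[length(out) + 1L]] <- data.frame(
        start = s0, end = e0,
        gc_fraction = unname(st["gc"]), obs_exp_cpg = unname(st["oe"]))
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
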
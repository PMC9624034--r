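# Shared internal helpers: argument checking, rank tests, TSV io.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

#' Two-sided Mann-Whitney U test with exact/approximate switch
#'
#' Exact null distribution is used when the combined sample size is at most
#' `exact_max` and there are no ties; otherwise the normal approximation with
#' tie correction (and continuity correction) is used. Degenerate inputs where
#' every value is identical return p = 1.
#'
#' @param x,y numeric vectors for the two groups (NAs dropped).
#' @param paired use the Wilcoxon signed-rank variant for paired samples.
#' @param exact_max combined-size bound below which the exact distribution is
#'   used (no ties only).
#' @return list with `statistic` (U, or V if paired) and `p`.
#' @keywords internal
mw_test <- function(x, y, paired = FALSE, exact_max = 12L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!paired && (length(x) < 1L || length(y) < 1L)) {
    return(list(statistic = NA_real_, p = NA_real_))
  }
  if (length(unique(c(x, y))) <= 1L) {
    st <- if (paired) 0 else length(x) * length(y) / 2
    return(list(statistic = st, p = 1))
  }
  exact <- (length(x) + length(y)) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       paired = paired, exact = exact)
  )
  p <- ht$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(ht$statistic), p = min(p, 1))
}

#' Benjamini-Hochberg adjustment preserving NA
#' @keywords internal
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop2("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Matrix + group-label bundle used by both omics matrices.
check_group_matrix <- function(mat, group, what = "matrix") {
  if (!is.matrix(mat)) stop2("%s must be a matrix", what)
  group <- as.character(group)
  if (length(group) != ncol(mat)) {
    stop2("%s: group labels (%d) do not match columns (%d)",
          what, length(group), ncol(mat))
  }
  bad <- setdiff(unique(group), c("tumor", "normal"))
  if (length(bad)) stop2("%s: unknown group label(s): %s", what,
                         paste(bad, collapse = ", "))
  if (!any(group == "tumor") || !any(group == "normal")) {
    stop2("%s: both tumor and normal groups must be non-empty", what)
  }
  if (anyDuplicated(rownames(mat))) stop2("%s: duplicated row ids", what)
  if (anyDuplicated(colnames(mat))) stop2("%s: duplicated sample ids", what)
  group
}
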
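# ROC analysis with Youden-index cut-off selection for a continuous
# diagnostic marker (e.g. promoter methylation rate) against binary labels.

#' Receiver operating characteristic curve
#'
#' Thresholds are placed at the midpoints between consecutive distinct
#' marker values, plus -Inf/+Inf sentinels; a sample is predicted positive
#' when its value is `>=` the threshold (for `positive_high = TRUE`, the
#' hypermethylation-is-disease orientation; set `FALSE` for markers that
#' decrease in cases). The midpoint construction makes cut-offs independent
#' of sample order and handles ties exactly: the trapezoid area under the
#' (1 - specificity, sensitivity) curve equals the Mann-Whitney U statistic
#' scaled by `n1 * n0`, with ties credited 0.5.
#'
#' @param values numeric marker vector, no missing values.
#' @param labels class labels; `TRUE`/1/"tumor" = positive class.
#' @param positive_high higher marker values indicate the positive class.
#' @return list of class `roc_result`: `thresholds` (ascending), `sens`,
#'   `spec` (aligned with thresholds), `auc`, `youden_cutoff`, `youden_j`,
#'   `sens_at_cutoff`, `spec_at_cutoff`.
#' @export
roc <- function(values, labels, positive_high = TRUE) {
  if (anyNA(values) || anyNA(labels)) stop2("missing values not allowed")
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "tumor"
  }
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop2("both classes must be present")
  v <- if (positive_high) values else -values

  sv <- sort(unique(v))
  mids <- if (length(sv) > 1L) (sv[-1] + sv[-length(sv)]) / 2 else numeric()
  thresholds <- c(-Inf, mids, Inf)
  sens <- vapply(thresholds, function(t) sum(v >= t & labels) / n1, numeric(1))
  spec <- vapply(thresholds, function(t) sum(v < t & !labels) / n0, numeric(1))

  # trapezoid over the ROC curve, points ordered by increasing FPR
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)

  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-9)   # tolerance absorbs division round-off
  if (length(best) > 1L) {                      # higher sens, then lower cutoff
    best <- best[order(-sens[best], thresholds[best])][1]
  }
  cutoff <- thresholds[best]
  if (!positive_high) {
    cutoff <- -cutoff
    thresholds_out <- rev(-thresholds)
    sens_out <- rev(sens); spec_out <- rev(spec)
  } else {
    thresholds_out <- thresholds
    sens_out <- sens; spec_out <- spec
  }
  structure(list(thresholds = thresholds_out, sens = sens_out,
                 spec = spec_out, auc = auc,
                 youden_cutoff = cutoff, youden_j = j[best],
                 sens_at_cutoff = sens[best], spec_at_cutoff = spec[best],
                 positive_high = positive_high),
            class = "roc_result")
}

#' Youden-index optimal cut-off
#'
#' Returns the threshold maximizing J = sensitivity + specificity - 1, with
#' ties broken by higher sensitivity and then lower cut-off. The reported
#' cut-off is the midpoint threshold itself.
#'
#' @param r `roc_result` from [roc()].
#' @return list with `cutoff`, `j`, `sens`, `spec`.
#' @export
youden <- function(r) {
  stopifnot(inherits(r, "roc_result"))
  list(cutoff = r$youden_cutoff, j = r$youden_j,
       sens = r$sens_at_cutoff, spec = r$spec_at_cutoff)
}
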
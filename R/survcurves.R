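# Kaplan-Meier estimation and two-group log-rank testing for dichotomized
# methylation/expression markers. Estimation and testing are delegated to
# the survival package; this module fixes the marker-split convention and
# the output shapes used by the pipeline.

#' Dichotomize a continuous marker
#'
#' `group = "high"` when `marker > median` (strict; a value equal to the
#' median goes to `"low"`), with the median taken as the
#' average-of-middle-two convention of [stats::median()]. An optional
#' `quantile` other than 0.5 moves the split point.
#'
#' @param records data.frame with at least a `marker` column.
#' @param rule split rule; only `"median"` (optionally at another
#'   `quantile`) is implemented.
#' @param quantile split quantile (default 0.5).
#' @return `records` with an added `group` column (`"high"`/`"low"`); split
#'   value and group sizes attached as attribute `"split"`.
#' @export
dichotomize <- function(records, rule = "median", quantile = 0.5) {
  rule <- match.arg(rule, "median")
  m <- records$marker
  if (anyNA(m)) stop2("missing marker values")
  if (length(unique(m)) < 2L) stop2("all marker values are equal; cannot split")
  cut <- unname(stats::quantile(m, quantile, type = 7))
  records$group <- ifelse(m > cut, "high", "low")
  attr(records, "split") <- list(value = cut,
                                 n_high = sum(records$group == "high"),
                                 n_low = sum(records$group == "low"))
  records
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate `S(t) = prod_{t_k <= t} (1 - d_k / n_k)` over the
#' distinct event times, with subjects censored at an event time still
#' counted at risk at that time.
#'
#' @param records data.frame with columns `time` (> 0) and `event`
#'   (1 = death, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` — one row per distinct observed time (event or censoring).
#' @export
km_curve <- function(records) {
  if (any(records$time <= 0)) stop2("times must be > 0")
  if (!all(records$event %in% c(0, 1))) stop2("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank test: observed minus expected events summed over event
#' times with hypergeometric variance, compared to a 1-df chi-square.
#'
#' @param records data.frame with columns `time`, `event`, `group` (two
#'   levels, e.g. `"high"`/`"low"`).
#' @return list with `chi_square`, `p`, `n` (per-group sizes), `obs`,
#'   `exp` (per-group observed and expected events).
#' @export
logrank <- function(records) {
  g <- unique(records$group)
  if (length(g) != 2L) stop2("exactly two groups required (got %d)", length(g))
  if (sum(records$event) < 1L) stop2("at least one event is required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       n = as.vector(sd$n), obs = as.vector(sd$obs),
       exp = as.vector(sd$exp))
}
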
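#' Median split into high and low groups
#'
#' Samples strictly above the median are `high`; samples at or below the
#' median are `low`. With all-distinct scores and even n this gives equal
#' halves; ties at the median all go to `low`, keeping `high` strictly above
#' the median.
#'
#' @param scores Numeric vector (length >= 2).
#' @return Character vector of `"high"`/`"low"` labels, named like `scores`.
#' @export
median_split <- function(scores) {
  stopifnot(length(scores) >= 2)
  m <- stats::median(scores)
  labels <- ifelse(scores > m, "high", "low")
  names(labels) <- names(scores)
  labels
}

#' Administrative censoring at a fixed horizon
#'
#' Any record with follow-up beyond the cutoff is treated as alive at the
#' cutoff: its time becomes the cutoff and its event flag 0. Records at or
#' below the cutoff are unchanged; the operation is idempotent. The study
#' convention is a 60-month horizon.
#'
#' @param tbl data.frame with columns `time` (months) and `event` (0/1).
#' @param cutoff_months Censoring horizon in months (default 60).
#' @return The table with censoring applied.
#' @export
administrative_censor <- function(tbl, cutoff_months = 60) {
  stopifnot(cutoff_months > 0, all(c("time", "event") %in% names(tbl)))
  late <- tbl$time > cutoff_months
  tbl$event[late] <- 0L
  tbl$time[late] <- cutoff_months
  tbl
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' event times, computed with [survival::survfit()]. Censored-only times
#' reduce the risk set without a step.
#'
#' @param tbl data.frame with columns `time` (>= 0) and `event` (0/1),
#'   optionally `group` for stratified curves.
#' @return data.frame of class `KMCurve` with columns `group` (if present),
#'   `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(tbl) {
  stopifnot(nrow(tbl) >= 1, all(c("time", "event") %in% names(tbl)))
  if (any(tbl$time < 0)) stop("negative survival time")
  if (!all(tbl$event %in% c(0, 1))) stop("event flags must be 0/1")
  has_group <- "group" %in% names(tbl)
  fit <- if (has_group) {
    survival::survfit(survival::Surv(time, event) ~ group, data = tbl)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = tbl)
  }
  s <- summary(fit, censored = TRUE)
  out <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                    surv = s$surv, stringsAsFactors = FALSE)
  if (has_group) {
    out <- cbind(group = sub("^group=", "", as.character(s$strata)), out,
                 stringsAsFactors = FALSE)
  }
  class(out) <- c("KMCurve", "data.frame")
  out
}

#' Mantel-Cox (log-rank) test between two groups
#'
#' Standard two-group log-rank test via [survival::survdiff()]: at each
#' event time the expected events follow the hypergeometric distribution;
#' the statistic `(O - E)^2 / V` is referred to chi-squared with 1 degree
#' of freedom (two-sided).
#'
#' @param tbl data.frame with columns `time`, `event`, `group` (exactly two
#'   non-empty groups).
#' @return list with `statistic` (chi-squared), `p_value`, `observed` and
#'   `expected` event counts per group.
#' @export
logrank_test <- function(tbl) {
  stopifnot(all(c("time", "event", "group") %in% names(tbl)))
  groups <- unique(tbl$group)
  if (length(groups) != 2L) stop("exactly two groups required")
  if (any(table(tbl$group) == 0L)) stop("empty group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = tbl)
  stat <- sd$chisq
  list(statistic = unname(stat),
       p_value = unname(stats::pchisq(stat, df = 1, lower.tail = FALSE)),
       observed = sd$obs, expected = sd$exp)
}

#' Median-split survival analysis of a scored cohort
#'
#' The study's survival stratification in one call: administrative
#' censoring at the horizon, median split of the score into high/low
#' groups, Kaplan-Meier curves per group and the Mantel-Cox log-rank test.
#'
#' @param tbl data.frame with columns `time`, `event`, `score`.
#' @param cutoff_months Censoring horizon (default 60).
#' @return list with `table` (censored, with `group` labels), `km`
#'   ([km_estimate()] per group) and `logrank` ([logrank_test()]).
#' @export
survival_by_median_score <- function(tbl, cutoff_months = 60) {
  stopifnot(all(c("time", "event", "score") %in% names(tbl)))
  tbl <- administrative_censor(tbl, cutoff_months)
  tbl$group <- median_split(tbl$score)
  list(table = tbl, km = km_estimate(tbl), logrank = logrank_test(tbl))
}
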
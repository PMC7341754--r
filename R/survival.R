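#' Derive overall-survival and event-free-survival records
#'
#' Overall survival (OS) runs from diagnosis to death from any cause, with
#' censoring at last follow-up. Event-free survival (EFS) runs from diagnosis
#' to the first event among relapse, failure to achieve remission, second
#' malignancy, or death; failure to achieve remission is scored as an event
#' on day 0. All day columns are days since diagnosis.
#'
#' @param metadata data.frame with columns `sample_id`, `follow_up_days`,
#'   and optionally `death_day`, `relapse_day`, `second_malignancy_day`
#'   (`NA` when the event did not occur), logical `remission_failure`, and
#'   `group`.
#' @return data.frame of `SurvivalRecord`s in long form: `sample_id`,
#'   `endpoint` (`"OS"`/`"EFS"`), `time` (days), `event` (logical), `group`.
#' @export
derive_survival_records <- function(metadata) {
  stopifnot(all(c("sample_id", "follow_up_days") %in% names(metadata)))
  n <- nrow(metadata)
  col <- function(nm, default) {
    if (nm %in% names(metadata)) metadata[[nm]] else rep(default, n)
  }
  death <- col("death_day", NA_real_)
  relapse <- col("relapse_day", NA_real_)
  second <- col("second_malignancy_day", NA_real_)
  remfail <- isTRUE_vec(col("remission_failure", FALSE), n)
  fup <- metadata$follow_up_days
  group <- col("group", NA_character_)
  days <- cbind(death, relapse, second, fup)
  if (any(days < 0, na.rm = TRUE)) stop("event date before diagnosis")

  os_event <- !is.na(death)
  os_time <- ifelse(os_event, death, fup)

  first_event <- suppressWarnings(pmin(relapse, second, death, na.rm = TRUE))
  efs_event <- is.finite(first_event) | remfail
  efs_time <- ifelse(remfail, 0, ifelse(is.finite(first_event), first_event, fup))

  rbind(
    data.frame(sample_id = metadata$sample_id, endpoint = "OS",
               time = os_time, event = os_event, group = group,
               stringsAsFactors = FALSE),
    data.frame(sample_id = metadata$sample_id, endpoint = "EFS",
               time = efs_time, event = efs_event, group = group,
               stringsAsFactors = FALSE)
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator for one group; subjects censored at an
#' event time remain at risk for that event (events precede censoring at
#' ties). The curve starts at 1 and is non-increasing.
#'
#' @param time follow-up times (days), `>= 0`.
#' @param event logical/0-1 event indicators.
#' @return data.frame: `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   one row per observed time.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, all(time >= 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Log-rank test between survival curves
#'
#' Standard log-rank statistic with hypergeometric variance across the
#' pooled event times; df = number of groups - 1, p from the chi-square
#' distribution.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param group group labels (2 or more groups, each non-empty).
#' @return list with `statistic`, `df`, `pvalue`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("log-rank needs at least 2 groups")
  if (sum(event) == 0) stop("no events observed; log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       pvalue = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}
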
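#' Confusion counts for a trigger rule
#'
#' Cross-tabulates alerts against observation-set labels. The unit of
#' analysis is a single observation set; neutralized sets must have been
#' excluded upstream (their presence is an error).
#'
#' @param data Data frame with `total`, `max_single` and `label` columns,
#'   `label` in `{"event", "non_event"}`.
#' @param rule A [trigger_rule()] row.
#' @return One-row tibble with `alerts`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(data, rule) {
  assert_columns(data, c("total", "max_single", "label"), "labeled scores")
  if (nrow(data) == 0L) abort("confusion_counts: empty input")
  bad <- setdiff(unique(data$label), c("event", "non_event"))
  if (length(bad) > 0L) {
    abort(sprintf("labels must be event/non_event (neutralized sets are excluded upstream); found: %s",
                  paste(bad, collapse = ", ")))
  }
  alert <- evaluate_trigger(data$total, data$max_single, rule)
  event <- data$label == "event"
  tibble(
    alerts = sum(alert),
    tp = sum(alert & event),
    fp = sum(alert & !event),
    tn = sum(!alert & !event),
    fn = sum(!alert & event)
  )
}

#' Threshold performance metrics from confusion counts
#'
#' Standard ratios plus the number-needed-to-evaluate, NNE = alerts per
#' true-positive alert = (TP + FP) / TP = 1 / PPV. Metrics with a zero
#' denominator are reported as `NA` (undefined), never silently 0.
#'
#' @param counts One-row data frame with `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusion_counts()]).
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `nne`.
#' @examples
#' threshold_metrics(tibble::tibble(tp = 228, fp = 231, tn = 0, fn = 0))$nne
#' @export
threshold_metrics <- function(counts) {
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  with(counts, tibble(
    accuracy = ratio(tp + tn, tp + fp + tn + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    nne = ratio(tp + fp, tp)
  ))
}

#' Alert-burden metrics per 100 patient-days
#'
#' The rate-of-alerts ROA = 100 x alerts / patient-days and the
#' alerted-outcome-event-rate AOER = 100 x TP / patient-days, so that
#' AOER = PPV x ROA and NNE = ROA / AOER.
#'
#' @param counts One-row data frame with `tp` and `fp` (or `alerts`).
#' @param patient_days Total patient-days at risk (> 0).
#' @return One-row tibble with `roa`, `aoer`.
#' @export
burden_metrics <- function(counts, patient_days) {
  if (!is.numeric(patient_days) || length(patient_days) != 1L || patient_days <= 0) {
    abort("patient_days must be a single positive number")
  }
  alerts <- counts$alerts %||% (counts$tp + counts$fp)
  tibble(
    roa = 100 * alerts / patient_days,
    aoer = 100 * counts$tp / patient_days
  )
}

#' Rescale a per-100-patient-day rate to a ward rate
#'
#' Expresses ROA/AOER-style rates as expected counts during a period on a
#' ward of a given size: a fully occupied 24-bed ward accrues 24
#' patient-days per 24 hours, so the per-100-patient-day rate is multiplied
#' by `beds x (hours / 24) / 100`.
#'
#' @param rate_per_100pd Rate per 100 patient-days.
#' @param beds Ward size (default 24 beds).
#' @param hours Period length in hours (default 24).
#' @return Expected number of alerts/events on the ward over the period.
#' @examples
#' ward_rate(8.906) # alerts per 24 h on a 24-bed ward
#' @export
ward_rate <- function(rate_per_100pd, beds = 24, hours = 24) {
  rate_per_100pd * beds * (hours / 24) / 100
}

#' Alarm cost of one additional detected event
#'
#' When moving between two trigger rules changes the ward-level rate of
#' alerts by `roa_increment` and the ward-level alerted-outcome-event rate
#' by `aoer_increment` (same time basis), the number of additional alarms
#' generated per additional detected true event is their ratio; all but one
#' of those alarms are false positives.
#'
#' @param roa_increment Increase in alerts per period.
#' @param aoer_increment Increase in detected (true-positive) events per
#'   period (> 0).
#' @return One-row tibble with `alarms_per_event` and
#'   `false_alarms_per_event` (= `alarms_per_event - 1`).
#' @examples
#' burden_tradeoff(1.463, 0.102) # ~14 alarms, ~13 false, per extra event
#' @export
burden_tradeoff <- function(roa_increment, aoer_increment) {
  stopifnot(aoer_increment > 0)
  tibble(
    alarms_per_event = roa_increment / aoer_increment,
    false_alarms_per_event = roa_increment / aoer_increment - 1
  )
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation, which equals the
#' probability that a randomly chosen event observation set scores higher
#' than a randomly chosen non-event set, with half credit for ties -- and
#' equals the trapezoidal area under the empirical ROC curve.
#'
#' @param score Numeric score vector (higher = more abnormal).
#' @param label Labels: logical, or character in `{"event", "non_event"}`.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(3, 1, 2, 2), c("event", "non_event", "non_event", "event")) # 0.875
#' @export
auroc <- function(score, label) {
  event <- .as_event(label)
  n1 <- sum(event); n0 <- sum(!event)
  if (n1 == 0L || n0 == 0L) abort("auroc: both classes must be present")
  r <- rank(score, ties.method = "average")
  (sum(r[event]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @noRd
.as_event <- function(label) {
  if (is.logical(label)) return(label)
  bad <- setdiff(unique(as.character(label)), c("event", "non_event"))
  if (length(bad) > 0L) abort(sprintf("unknown labels: %s", paste(bad, collapse = ", ")))
  as.character(label) == "event"
}

#' ROC curve points
#'
#' Sweeps alert thresholds over all observed scores (alert when
#' `score >= threshold`), plus sentinel thresholds yielding the (0,0) and
#' (1,1) corners.
#'
#' @inheritParams auroc
#' @return Tibble with `threshold`, `sensitivity`, `specificity`, `fpr`.
#' @export
roc_points <- function(score, label) {
  event <- .as_event(label)
  n1 <- sum(event); n0 <- sum(!event)
  if (n1 == 0L || n0 == 0L) abort("roc_points: both classes must be present")
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  purrr::map_dfr(thr, function(th) {
    alert <- score >= th
    tibble(
      threshold = th,
      sensitivity = sum(alert & event) / n1,
      specificity = sum(!alert & !event) / n0,
      fpr = sum(alert & !event) / n0
    )
  })
}

#' Area under the precision-recall curve
#'
#' Non-interpolated average precision: thresholds descend over the unique
#' observed scores and each recall increment is weighted by the precision at
#' that threshold, `AP = sum_i (R_i - R_{i-1}) P_i`. With all scores equal
#' this reduces exactly to the event prevalence. Linear interpolation in PR
#' space is deliberately not used (it is biased for imbalanced outcomes).
#'
#' @inheritParams auroc
#' @return Average precision in `[0, 1]`.
#' @examples
#' pr_auc(c(3, 1, 2, 2), c("event", "non_event", "non_event", "event")) # 5/6
#' @export
pr_auc <- function(score, label) {
  pts <- pr_points(score, label)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' @rdname pr_auc
#' @return For `pr_points`: tibble with `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(score, label) {
  event <- .as_event(label)
  n1 <- sum(event)
  if (n1 == 0L) abort("pr_points: at least one event is required")
  thr <- sort(unique(score), decreasing = TRUE)
  purrr::map_dfr(thr, function(th) {
    alert <- score >= th
    tibble(
      threshold = th,
      recall = sum(alert & event) / n1,
      precision = sum(alert & event) / sum(alert)
    )
  })
}

#' Expected number of events for a cohort
#'
#' Sample-size arithmetic for a Poisson event process: with `n_patients`
#' staying `mean_stay` days each and an event rate per patient-day, the
#' expected event count is their product (e.g. 500 patients x 10 days x
#' 0.005 events/patient-day = 25 events).
#'
#' @param n_patients Number of patients (>= 0).
#' @param mean_stay Mean length of stay in days (> 0).
#' @param rate Events per patient-day (> 0).
#' @return Expected number of events.
#' @export
expected_event_count <- function(n_patients, mean_stay, rate) {
  stopifnot(n_patients >= 0, mean_stay > 0, rate > 0)
  n_patients * mean_stay * rate
}

#' Per-rule performance and burden report
#'
#' Convenience wrapper applying [confusion_counts()], [threshold_metrics()]
#' and [burden_metrics()] for each rule in a rule set.
#'
#' @param data Labeled scores with per-score totals: columns
#'   `total_<score>` and `max_single_<score>` for each distinct `score` in
#'   `rules`, plus `label`.
#' @param rules Tibble of [trigger_rule()] rows.
#' @param patient_days Denominator for burden metrics.
#' @return Tibble with one row per rule: counts, threshold metrics, `roa`,
#'   `aoer`.
#' @export
rule_metrics <- function(data, rules, patient_days) {
  purrr::pmap_dfr(rules, function(name, score, threshold, s3) {
    cols <- paste0(c("total_", "max_single_"), score)
    assert_columns(data, cols, "labeled scores")
    d <- tibble(total = data[[cols[1]]], max_single = data[[cols[2]]],
                label = data$label)
    counts <- confusion_counts(d, list(threshold = threshold, s3 = s3))
    dplyr::bind_cols(
      tibble(rule = name, score = score, threshold = threshold, s3 = s3),
      counts, threshold_metrics(counts), burden_metrics(counts, patient_days)
    )
  })
}
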
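#' Per-shark detection metrics
#'
#' Computes, for every tagged shark, the detection tallies that all
#' residency analysis rests on:
#' * `n_detections` - detections array-wide;
#' * `n_detection_days` - local calendar days with two or more detections;
#' * `detection_period_days` - days elapsed between tagging and last
#'   detection (0 for a shark last heard on its tagging day);
#' * `n_detection_months` - distinct calendar months (year x month) holding
#'   at least one detection day;
#' * `monitoring_period_days` - expected tag life truncated at study end
#'   (see [monitoring_period()]).
#'
#' Sharks never detected appear with zero counts and `NA` period. Detections
#' time-stamped before a shark's tagging date are excluded with a warning.
#'
#' @param dets Pre-processed detections (`tag_id`, `date_local`).
#' @param sharks Shark metadata tibble (`tag_id`, `tagging_date`,
#'   `tag_life_days`, ...).
#' @param config A [study_config()].
#' @return One tibble row per shark in `sharks`.
#' @export
detection_metrics <- function(dets, sharks, config) {
  sharks <- mutate(sharks, tagging_date = as.Date(.data$tagging_date))
  dets <- semi_join(dets, sharks, by = "tag_id") %>%
    left_join(select(sharks, "tag_id", "tagging_date"), by = "tag_id")
  pre_tag <- sum(dets$date_local < dets$tagging_date)
  if (pre_tag > 0) {
    warn(sprintf("Excluded %d detection(s) earlier than the tagging date.", pre_tag))
    dets <- filter(dets, .data$date_local >= .data$tagging_date)
  }

  day_counts <- dets %>%
    count(.data$tag_id, .data$date_local, name = "n_day")
  per_tag <- day_counts %>%
    group_by(.data$tag_id) %>%
    summarise(
      n_detections = sum(.data$n_day),
      n_detection_days = sum(.data$n_day >= 2L),
      last_detection = max(.data$date_local),
      n_detection_months = n_distinct(format(.data$date_local[.data$n_day >= 2L], "%Y-%m")),
      .groups = "drop"
    )

  sharks %>%
    select("tag_id", "tagging_date", "tag_life_days") %>%
    left_join(per_tag, by = "tag_id") %>%
    mutate(
      n_detections = dplyr::coalesce(.data$n_detections, 0L),
      n_detection_days = dplyr::coalesce(.data$n_detection_days, 0L),
      n_detection_months = dplyr::coalesce(.data$n_detection_months, 0L),
      detection_period_days = as.integer(.data$last_detection - .data$tagging_date),
      monitoring_period_days = monitoring_period(.data$tagging_date,
                                                 .data$tag_life_days, config)
    ) %>%
    select("tag_id", "tagging_date", "n_detections", "n_detection_days",
           "last_detection", "detection_period_days", "n_detection_months",
           "monitoring_period_days")
}

#' Monitoring period of a tag
#'
#' The number of days a tag could have been detected: the expected battery
#' life, truncated at the end of the study for tags whose battery outlives
#' the monitoring (`min(tag_life_days, study_end - tagging_date)`). This is
#' the denominator of the Residency Index.
#'
#' @param tagging_date Date vector.
#' @param tag_life_days Positive integer vector.
#' @param config A [study_config()].
#' @return Integer vector of days; errors if any value is non-positive.
#' @examples
#' cfg <- study_config("2010-10-01", "2019-06-30")
#' monitoring_period(as.Date("2012-06-01"), 1237, cfg)
#' @export
monitoring_period <- function(tagging_date, tag_life_days, config) {
  to_end <- as.integer(config$study_end - as.Date(tagging_date))
  out <- pmin(as.integer(tag_life_days), to_end)
  if (any(out <= 0, na.rm = TRUE)) {
    abort("Non-positive monitoring period: tagging on/after study end or bad tag life.")
  }
  out
}

#' Residency Index
#'
#' `RI = detection days / monitoring period`, in `[0, 1]`: the fraction of
#' the days a tag could have been detected on which its shark actually was
#' (with >= 2 detections). 1 means detected every single day from tagging to
#' the end of tag life; values are kept at full precision and only rounded
#' for display.
#'
#' @param n_detection_days Non-negative counts.
#' @param monitoring_period_days Positive day counts.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' residency_index(595, 1237) # 0.4810
#' @export
residency_index <- function(n_detection_days, monitoring_period_days) {
  if (any(monitoring_period_days <= 0, na.rm = TRUE)) {
    abort("monitoring_period_days must be positive.")
  }
  n_detection_days / monitoring_period_days
}

#' Classification of Residency
#'
#' Rule-based behavioural classification of each detected shark into one of
#' four exclusive categories:
#' * **Passer-by** - never detected after the first 30-day "Month" block
#'   post tagging;
#' * **Transient** - detected beyond the first Month block but over fewer
#'   than three detection months in total (typically re-detected after a
#'   gap longer than a Month of absence);
#' * **Pseudo-resident** - three or more detection months, present on
#'   < 30% of the days of its detection period;
#' * **Resident** - three or more detection months, present on >= 30% of
#'   its detection period (equality assigned to Resident).
#'
#' Sharks with zero detection days are returned with `NA` class (absent
#' from residency analysis).
#'
#' @param metrics Output of [detection_metrics()].
#' @param config A [study_config()] (`month_block_days`,
#'   `presence_threshold_pct`).
#' @return `metrics` with added columns `ri`, `presence_pct` and `cr`
#'   (factor with levels `Pass.-by`, `Trans.`, `Ps.-res.`, `Resident`).
#' @export
classify_residency <- function(metrics, config) {
  lv <- c("Pass.-by", "Trans.", "Ps.-res.", "Resident")
  metrics %>%
    mutate(
      ri = if_else(.data$n_detection_days > 0,
                   residency_index(.data$n_detection_days, .data$monitoring_period_days),
                   NA_real_),
      presence_pct = if_else(.data$detection_period_days > 0,
                             100 * .data$n_detection_days / .data$detection_period_days,
                             NA_real_),
      cr = factor(dplyr::case_when(
        .data$n_detection_days == 0L ~ NA_character_,
        .data$last_detection <= .data$tagging_date + config$month_block_days ~ "Pass.-by",
        .data$n_detection_months < 3L ~ "Trans.",
        dplyr::coalesce(.data$presence_pct, 100) >= config$presence_threshold_pct ~ "Resident",
        TRUE ~ "Ps.-res."
      ), levels = lv)
    )
}

#' Cohort summary of detection metrics
#'
#' Summarises a tagged cohort the way telemetry studies report it: means,
#' standard errors and ranges of detections, detection days and detection
#' period over *all* tagged sharks (never-detected individuals enter as
#' zeros), and of the Residency Index over *detected* sharks only (RI is
#' undefined for sharks never heard). Also tallies the residency classes.
#'
#' @param residency Output of [classify_residency()] covering the full
#'   tagged cohort.
#' @return A one-row tibble with `n_tagged`, `n_detected` and
#'   mean/SE/min/max columns; the class tally is attached as attribute
#'   `"cr_counts"`.
#' @export
cohort_summary <- function(residency) {
  if (nrow(residency) == 0) abort("Empty cohort.")
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  det <- filter(residency, .data$n_detection_days > 0)
  period0 <- dplyr::coalesce(residency$detection_period_days, 0L)
  out <- tibble(
    n_tagged = nrow(residency),
    n_detected = sum(residency$n_detections > 0),
    mean_detections = mean(residency$n_detections),
    se_detections = se(residency$n_detections),
    max_detections = max(residency$n_detections),
    mean_detection_days = mean(residency$n_detection_days),
    se_detection_days = se(residency$n_detection_days),
    max_detection_days = max(residency$n_detection_days),
    mean_detection_period = mean(period0),
    se_detection_period = se(period0),
    max_detection_period = max(period0),
    mean_ri = mean(det$ri),
    se_ri = se(det$ri),
    min_ri = if (nrow(det)) min(det$ri) else NA_real_,
    max_ri = if (nrow(det)) max(det$ri) else NA_real_
  )
  attr(out, "cr_counts") <- table(residency$cr, useNA = "ifany")
  out
}
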
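#' Study configuration
#'
#' Bundles the analysis conventions used throughout the pipeline: the fixed
#' UTC offset of the study area, the study window, season and diel-period
#' definitions, the 30-day "Month" block used by the residency classifier,
#' the minimum deployment duration for a station to enter the analysis, and
#' the presence threshold separating resident from pseudo-resident behaviour.
#'
#' The defaults mirror a Caribbean deployment: local time is UTC-5 with no
#' daylight saving, summer is April-September, day runs 06:30-18:29 local,
#' and stations need six months (180 working days) of functioning receiver
#' coverage to be analysed.
#'
#' @param study_start,study_end Date (or coercible). Bounds of the analysis
#'   window; detections and deployments are clipped to it.
#' @param utc_offset_hours Integer hours added to UTC to obtain local time
#'   (default `-5`).
#' @param summer_months Integer months making up "summer" (default `4:9`,
#'   April-September); the remaining months are winter.
#' @param day_start,day_end Character `"HH:MM"` local clock bounds of the day
#'   diel period, inclusive (default `"06:30"` to `"18:29"`; night is the
#'   complement).
#' @param month_block_days Length in days of the classifier's "Month" block
#'   counted from tagging (default 30).
#' @param min_station_months Minimum months of working-receiver coverage for
#'   a station to be retained (default 6; one month counts as 30 days).
#' @param presence_threshold_pct Presence percentage (detection days /
#'   detection period x 100) at or above which a shark with >= 3 detection
#'   months is classed Resident rather than Pseudo-resident (default 30).
#' @param station_day_min_detections Minimum detections at a single station
#'   on one local day for a station-level detection day (default 2, parallel
#'   to the array-wide rule).
#' @param max_bad_timestamp_frac Tolerated fraction of unparseable timestamp
#'   rows when reading a detection file before the load aborts (default 0.05).
#' @param rng_seed Integer seed used by seeded downstream routines.
#'
#' @return A list with class `"study_config"`.
#' @examples
#' cfg <- study_config(study_start = "2010-10-01", study_end = "2019-06-30")
#' cfg$summer_months
#' @export
study_config <- function(study_start,
                         study_end,
                         utc_offset_hours = -5L,
                         summer_months = 4:9,
                         day_start = "06:30",
                         day_end = "18:29",
                         month_block_days = 30L,
                         min_station_months = 6L,
                         presence_threshold_pct = 30,
                         station_day_min_detections = 2L,
                         max_bad_timestamp_frac = 0.05,
                         rng_seed = 1L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (is.na(study_start) || is.na(study_end)) {
    abort("`study_start` and `study_end` must be valid dates.")
  }
  if (study_start >= study_end) {
    abort("`study_start` must be earlier than `study_end`.")
  }
  if (!all(summer_months %in% 1:12)) {
    abort("`summer_months` must be months in 1..12.")
  }
  cfg <- list(
    study_start = study_start,
    study_end = study_end,
    utc_offset_hours = as.integer(utc_offset_hours),
    summer_months = as.integer(summer_months),
    day_start = day_start,
    day_end = day_end,
    month_block_days = as.integer(month_block_days),
    min_station_months = as.integer(min_station_months),
    presence_threshold_pct = presence_threshold_pct,
    station_day_min_detections = as.integer(station_day_min_detections),
    max_bad_timestamp_frac = max_bad_timestamp_frac,
    rng_seed = as.integer(rng_seed)
  )
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  window      :", format(x$study_start), "to", format(x$study_end), "\n")
  cat("  local time  : UTC", sprintf("%+d", x$utc_offset_hours), "h\n")
  cat("  summer      : months", paste(x$summer_months, collapse = ","), "\n")
  cat("  day window  :", x$day_start, "-", x$day_end, "\n")
  cat("  month block :", x$month_block_days, "days;",
      "station minimum:", x$min_station_months, "months\n")
  invisible(x)
}

# minutes past local midnight for an "HH:MM" string
parse_clock_min <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.integer(parts[1]) * 60L + as.integer(parts[2])
}
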
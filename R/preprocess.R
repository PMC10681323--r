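#' Resolve raw detections to stations and local time
#'
#' Maps each raw detection to the station where its receiver serial was
#' deployed at the detection time, using the deployment calendar, and shifts
#' timestamps to local time with the study's fixed UTC offset. Detections
#' whose serial has no covering deployment interval are dropped and counted;
#' exact duplicate rows (same tag, serial, timestamp) are dropped first,
#' since overlapping receiver downloads commonly repeat records.
#'
#' A serial covered by two deployment intervals at the same instant is a
#' data-integrity error and aborts the run.
#'
#' @param raw Tibble from [read_detections()] (`timestamp_utc`,
#'   `receiver_serial`, `tag_id`).
#' @param deployments Deployment calendar tibble (`receiver_serial`,
#'   `station_id`, `start_date`, `end_date`; `NA` end = open).
#' @param stations Station table (`station_id`, `island`, `lat`, `lon`).
#' @param config A [study_config()].
#' @return Tibble of resolved detections: `tag_id`, `station_id`, `island`,
#'   `timestamp_local`, `date_local`, ordered by tag then time. Attributes
#'   `n_dropped_unresolved` and `n_dropped_duplicate` carry the drop counts.
#' @export
resolve_stations <- function(raw, deployments, stations, config) {
  stations <- validate_stations(stations)
  deployments <- validate_deployments(deployments)
  unknown <- setdiff(deployments$station_id, stations$station_id)
  if (length(unknown) > 0) {
    abort(paste0("Deployment calendar references unknown station(s): ",
                 paste(unknown, collapse = ", ")))
  }

  n_in <- nrow(raw)
  raw <- distinct(raw, .data$timestamp_utc, .data$receiver_serial, .data$tag_id)
  n_dup <- n_in - nrow(raw)
  if (n_dup > 0) inform(sprintf("Dropped %d duplicate detection row(s).", n_dup))

  raw <- mutate(raw,
    timestamp_local = .data$timestamp_utc + config$utc_offset_hours * 3600,
    date_local = as.Date(.data$timestamp_local, tz = "UTC")
  )

  cal <- mutate(deployments,
    end_closed = if_else(is.na(.data$end_date), as.Date("9999-12-31"), .data$end_date)
  )
  hit <- left_join(
    mutate(raw, .row = row_number()),
    cal,
    by = join_by(receiver_serial, between(date_local, start_date, end_closed)),
    relationship = "many-to-many"
  )
  dup_rows <- hit$.row[duplicated(hit$.row)]
  if (length(dup_rows) > 0) {
    bad <- hit[hit$.row == dup_rows[1], ]
    abort(sprintf(
      "Serial %s has overlapping deployment intervals covering %s.",
      bad$receiver_serial[1], format(bad$date_local[1])
    ))
  }
  n_unresolved <- sum(is.na(hit$station_id))
  if (n_unresolved > 0) {
    inform(sprintf("Dropped %d detection(s) with no covering deployment interval.",
                   n_unresolved))
  }
  out <- hit %>%
    filter(!is.na(.data$station_id)) %>%
    left_join(select(stations, "station_id", "island"), by = "station_id") %>%
    select("tag_id", "station_id", "island", "timestamp_local", "date_local") %>%
    arrange(.data$tag_id, .data$timestamp_local)
  attr(out, "n_dropped_unresolved") <- n_unresolved
  attr(out, "n_dropped_duplicate") <- n_dup
  out
}

#' Remove single-detection days
#'
#' Drops every detection of a tag on a local calendar day on which that tag
#' was detected exactly once array-wide. Isolated single receptions are the
#' classic false-detection signature of code collisions in acoustic
#' telemetry, and a lone detection can never contribute a detection day
#' (which requires two or more detections). The filter is idempotent and
#' preserves the order of the remaining rows.
#'
#' @param dets Resolved detections (needs `tag_id`, `date_local`).
#' @return Filtered tibble; attribute `"n_removed"` holds the removal count,
#'   attribute `"removed_by_tag"` a per-tag tally.
#' @export
remove_single_detections <- function(dets) {
  if (nrow(dets) == 0) {
    attr(dets, "n_removed") <- 0L
    return(dets)
  }
  out <- dets %>%
    group_by(.data$tag_id, .data$date_local) %>%
    filter(n() >= 2L) %>%
    ungroup()
  removed <- dets %>%
    group_by(.data$tag_id, .data$date_local) %>%
    filter(n() < 2L) %>%
    ungroup() %>%
    count(.data$tag_id, name = "n_removed")
  attr(out, "n_removed") <- nrow(dets) - nrow(out)
  attr(out, "removed_by_tag") <- removed
  out
}

#' Working days per station
#'
#' Counts, for every station, the calendar days within the study window on
#' which the station carried a functioning receiver according to the
#' deployment calendar. Intervals are inclusive at both ends (a deployment
#' `[d1, d2]` contributes `d2 - d1 + 1` days); overlapping intervals for a
#' station are counted once. Stations with fewer working days than
#' `min_station_months` x 30 are flagged `excluded` and are removed from
#' analysis by the pipeline.
#'
#' @param deployments Deployment calendar tibble.
#' @param config A [study_config()].
#' @return Tibble `station_id`, `working_days`, `excluded`.
#' @export
station_working_days <- function(deployments, config) {
  deployments <- validate_deployments(deployments)
  deployments %>%
    mutate(
      from = pmax(.data$start_date, config$study_start),
      to = pmin(if_else(is.na(.data$end_date), config$study_end, .data$end_date),
                config$study_end)
    ) %>%
    filter(.data$from <= .data$to) %>%
    group_by(.data$station_id) %>%
    summarise(
      working_days = length(unique(unlist(purrr::map2(
        .data$from, .data$to, ~ seq.int(as.integer(.x), as.integer(.y))
      )))),
      .groups = "drop"
    ) %>%
    mutate(excluded = .data$working_days < config$min_station_months * 30L)
}

#' Full detection pre-processing
#'
#' Convenience wrapper chaining the standardisation steps applied before any
#' metric is computed: duplicate removal and station resolution
#' ([resolve_stations()]), exclusion of stations with insufficient receiver
#' coverage ([station_working_days()]), and removal of single-detection days
#' ([remove_single_detections()]). Detections outside the study window are
#' dropped.
#'
#' @inheritParams resolve_stations
#' @return A list with `detections` (analysis-ready tibble), `working_days`
#'   (per-station coverage with exclusion flags), and `counts` (named drop
#'   counts per step).
#' @export
preprocess_detections <- function(raw, deployments, stations, config) {
  resolved <- resolve_stations(raw, deployments, stations, config)
  n_resolved <- nrow(resolved)
  in_window <- filter(resolved,
                      .data$date_local >= config$study_start,
                      .data$date_local <= config$study_end)
  wd <- station_working_days(deployments, config)
  keep <- wd$station_id[!wd$excluded]
  on_kept <- filter(in_window, .data$station_id %in% keep)
  filtered <- remove_single_detections(on_kept)
  list(
    detections = filtered,
    working_days = wd,
    counts = c(
      raw = nrow(raw),
      duplicate = attr(resolved, "n_dropped_duplicate"),
      unresolved = attr(resolved, "n_dropped_unresolved"),
      outside_window = n_resolved - nrow(in_window),
      excluded_station = nrow(in_window) - nrow(on_kept),
      single_detection = attr(filtered, "n_removed"),
      analysed = nrow(filtered)
    )
  )
}
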
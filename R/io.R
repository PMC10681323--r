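#' Read a receiver-download detection export
#'
#' Parses a detection CSV in the dialect of receiver-download software
#' exports: one row per logged transmission with a UTC timestamp, a receiver
#' identifier such as `VR2W-123456`, and a transmitter identifier such as
#' `A69-1602-28955`. The token after the final hyphen is taken as the
#' receiver serial / tag id; plain serials without hyphens pass through
#' unchanged.
#'
#' Rows whose timestamp cannot be parsed are collected and reported; the
#' load aborts when their fraction exceeds `config$max_bad_timestamp_frac`.
#'
#' @param path Path to the CSV file.
#' @param config A [study_config()] (used for the bad-row tolerance).
#' @param dialect Named list of column names:
#'   `timestamp` (default `"Date and Time (UTC)"`), `receiver`
#'   (`"Receiver"`), `transmitter` (`"Transmitter"`).
#' @return A tibble of raw detections with columns `timestamp_utc` (POSIXct,
#'   UTC), `receiver_serial`, `tag_id`. Rejected rows (with line numbers)
#'   are attached as attribute `"rejected"`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "Date and Time (UTC),Receiver,Transmitter",
#'   "2015-07-04 10:00:00,VR2W-101,A69-1602-9001"
#' ), f)
#' read_detections(f, study_config("2015-01-01", "2016-01-01"))
#' @export
read_detections <- function(path, config, dialect = list()) {
  if (!file.exists(path)) abort(paste0("Detection file not found: ", path))
  d <- list(
    timestamp = dialect$timestamp %||% "Date and Time (UTC)",
    receiver = dialect$receiver %||% "Receiver",
    transmitter = dialect$transmitter %||% "Transmitter"
  )
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(unlist(d), names(raw))
  if (length(missing) > 0) {
    abort(paste0("Detection file is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ts <- lubridate::ymd_hms(raw[[d$timestamp]], tz = "UTC", quiet = TRUE)
  bad <- which(is.na(ts))
  if (nrow(raw) > 0 && length(bad) / nrow(raw) > config$max_bad_timestamp_frac) {
    abort(sprintf(
      "%d of %d rows have unparseable timestamps (tolerance %.1f%%); first bad line: %d",
      length(bad), nrow(raw), 100 * config$max_bad_timestamp_frac, bad[1] + 1L
    ))
  }
  if (length(bad) > 0) {
    warn(sprintf("Dropped %d row(s) with unparseable timestamps (data lines: %s)",
                 length(bad), paste(head(bad + 1L, 10), collapse = ", ")))
  }
  out <- tibble(
    timestamp_utc = ts,
    receiver_serial = id_token(raw[[d$receiver]]),
    tag_id = id_token(raw[[d$transmitter]])
  )
  rejected <- out[bad, , drop = FALSE]
  rejected$line <- bad + 1L
  out <- out[setdiff(seq_len(nrow(out)), bad), , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

# final-hyphen token of a receiver/transmitter identifier
id_token <- function(x) sub(".*-", "", x)

#' Read station, deployment and shark metadata tables
#'
#' Readers for the three plain-CSV side tables the pipeline consumes:
#' * stations: `station_id,island,lat,lon`
#' * deployments: `receiver_serial,station_id,start_date,end_date`
#'   (empty `end_date` means the deployment is open-ended)
#' * sharks: `tag_id,sex,maturity,tl_cm,tagging_date,tagging_lat,
#'   tagging_lon,island,tag_type,tag_life_days`
#'
#' Basic integrity is enforced: coordinates in range, unique station and tag
#' ids, deployment intervals with `start_date <= end_date`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_stations <- function(path) {
  s <- readr::read_csv(path, col_types = "ccdd", progress = FALSE)
  validate_stations(s)
}

validate_stations <- function(s) {
  s <- as_tibble(s)
  req <- c("station_id", "island", "lat", "lon")
  if (!all(req %in% names(s))) {
    abort(paste0("Station table needs columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(s$station_id)) abort("Duplicate station_id in station table.")
  if (any(abs(s$lat) > 90 | abs(s$lon) > 180, na.rm = TRUE) || anyNA(s$lat) || anyNA(s$lon)) {
    abort("Station coordinates must be valid decimal degrees.")
  }
  s
}

#' @rdname read_tables
#' @export
read_deployments <- function(path) {
  d <- readr::read_csv(path, col_types = "ccDD", progress = FALSE)
  validate_deployments(d)
}

validate_deployments <- function(d) {
  d <- as_tibble(d)
  req <- c("receiver_serial", "station_id", "start_date", "end_date")
  if (!all(req %in% names(d))) {
    abort(paste0("Deployment table needs columns: ", paste(req, collapse = ", ")))
  }
  d$start_date <- as.Date(d$start_date)
  d$end_date <- as.Date(d$end_date)
  closed <- !is.na(d$end_date)
  if (any(d$start_date[closed] > d$end_date[closed])) {
    abort("Deployment intervals must have start_date <= end_date.")
  }
  d
}

#' @rdname read_tables
#' @export
read_sharks <- function(path) {
  s <- readr::read_csv(path, col_types = "cccdDddcci", progress = FALSE)
  validate_sharks(s)
}

validate_sharks <- function(s) {
  s <- as_tibble(s)
  req <- c("tag_id", "sex", "maturity", "tl_cm", "tagging_date",
           "tagging_lat", "tagging_lon", "island", "tag_type", "tag_life_days")
  if (!all(req %in% names(s))) {
    abort(paste0("Shark table needs columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(s$tag_id)) abort("Duplicate tag_id in shark table.")
  s$tagging_date <- as.Date(s$tagging_date)
  if (any(s$tl_cm <= 30 | s$tl_cm >= 400, na.rm = TRUE)) {
    abort("tl_cm outside plausible range (30, 400) cm.")
  }
  if (any(s$tag_life_days <= 0, na.rm = TRUE)) abort("tag_life_days must be positive.")
  s
}

#' Per-shark summary table from the Cayman Islands study
#'
#' The published per-shark summary of the 39 Caribbean reef sharks detected
#' on the Cayman Islands acoustic array (2010-2019): tag metadata, detection
#' counts, detection days/period/months, Residency Index, residency class,
#' minimum linear displacement, receivers and islands used, and the
#' Site-Fidelity Index of the primary receiver. Shipped as a plain-text
#' fixture so index arithmetic and cohort summaries can be validated against
#' printed values without the (undeposited) raw detection data.
#'
#' @return A 39-row tibble; `cr` uses the labels `Pass.-by`, `Trans.`,
#'   `Ps.-res.`, `Resident`.
#' @examples
#' t2 <- cayman_table2()
#' mean(t2$n_detection_days / t2$tag_life_days)
#' @export
cayman_table2 <- function() {
  path <- system.file("extdata", "cayman_table2.csv", package = "reeftrace",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "cccdicidiiidcdiid", progress = FALSE)
}
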
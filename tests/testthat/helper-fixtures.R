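# Tiny hand-built fixtures shared across test files. All data are built in
# code; coordinates are arbitrary points in the NW Caribbean.

toy_stations <- function() {
  tibble::tibble(
    station_id = c("A", "B", "C"),
    island = c("I1", "I1", "I2"),
    lat = c(19.30, 19.35, 19.70),
    lon = c(-81.20, -81.10, -80.00)
  )
}

toy_deployments <- function(start = "2015-01-01", end = "2016-12-31") {
  tibble::tibble(
    receiver_serial = c("101", "102", "103"),
    station_id = c("A", "B", "C"),
    start_date = as.Date(start),
    end_date = as.Date(end)
  )
}

toy_config <- function(...) {
  study_config("2015-01-01", "2016-12-31", ...)
}

# raw (UTC) detections
raw_det <- function(ts, serial, tag) {
  tibble::tibble(
    timestamp_utc = lubridate::ymd_hms(ts, tz = "UTC"),
    receiver_serial = serial,
    tag_id = tag
  )
}

# already-resolved local detections
loc_det <- function(ts, station, tag, island = "I1") {
  t <- lubridate::ymd_hms(ts, tz = "UTC")
  tibble::tibble(
    tag_id = tag, station_id = station, island = island,
    timestamp_local = t, date_local = as.Date(t, tz = "UTC")
  )
}

toy_shark <- function(tag, tagging = "2015-01-01", tl = 150, sex = "F",
                      maturity = "M", tag_life = 500,
                      lat = 19.30, lon = -81.20, island = "I1") {
  tibble::tibble(
    tag_id = tag, sex = sex, maturity = maturity, tl_cm = tl,
    tagging_date = as.Date(tagging), tagging_lat = lat, tagging_lon = lon,
    island = island, tag_type = ifelse(tl < 110, "V9", "V16"),
    tag_life_days = as.integer(tag_life)
  )
}

# n detections (n <= 59) of one tag at one station within one local day
day_of_dets <- function(date, station, tag, n, island = "I1") {
  loc_det(paste(date, sprintf("10:%02d:00", seq_len(n) - 1)),
          station, tag, island)
}

# compare tabular content, ignoring bookkeeping attributes like drop counts
expect_tbl_equal <- function(a, b, tol = 1e-10) {
  strip <- function(x) {
    x <- as.data.frame(x)
    attributes(x) <- attributes(x)[c("names", "class", "row.names")]
    x
  }
  expect_equal(strip(a), strip(b), tolerance = tol)
}
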
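#' Great-circle distance in kilometres
#'
#' Haversine distance between points on a sphere of radius 6371.0 km (the
#' convention of the standard aviation-formulary calculators). Vectorised
#' over coordinates; symmetric; zero only for identical points.
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees (WGS84).
#' @param radius_km Sphere radius, default 6371.0.
#' @return Distance(s) in km.
#' @examples
#' great_circle_km(19.3222, -81.2409, 19.7235, -79.8017) # Grand Cayman - Brac
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE) ||
      anyNA(c(lat1, lon1, lat2, lon2))) {
    abort("Coordinates must be valid decimal degrees.")
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  radius_km * 2 * asin(pmin(1, sqrt(a)))
}

#' Per-shark, per-station usage with Detection and Site-Fidelity indices
#'
#' For every shark x station pair tallies detections and station-level
#' detection days (days with at least `config$station_day_min_detections`
#' detections at that station), then computes:
#' * the **Detection Index** `DI = (station detections / shark total
#'   detections) x (station detection days / shark total detection days)`,
#'   a product of proportions that discounts stations visited briefly but
#'   pinged heavily (or vice versa);
#' * the **Site-Fidelity Index** `SFI = DI / sum(DI) x 100`, summing to
#'   100% over a shark's stations;
#' * the SFI **rank** (1 = primary receiver site; ties broken by
#'   station id for reproducibility).
#'
#' Shark totals are array-wide (total detections, total array-wide
#' detection days). Sharks whose DI is zero at every station (no station
#' ever logged the per-day minimum) get `NA` SFI and rank.
#'
#' @param dets Pre-processed detections.
#' @param config A [study_config()].
#' @return Tibble `tag_id`, `station_id`, `n_detections`,
#'   `n_detection_days`, `di`, `sfi`, `rank`.
#' @export
station_usage <- function(dets, config) {
  totals <- dets %>%
    count(.data$tag_id, .data$date_local, name = "n_day") %>%
    group_by(.data$tag_id) %>%
    summarise(tot_dets = sum(.data$n_day),
              tot_days = sum(.data$n_day >= 2L), .groups = "drop")

  usage <- dets %>%
    count(.data$tag_id, .data$station_id, .data$date_local, name = "n_day") %>%
    group_by(.data$tag_id, .data$station_id) %>%
    summarise(
      n_detections = sum(.data$n_day),
      n_detection_days = sum(.data$n_day >= config$station_day_min_detections),
      .groups = "drop"
    ) %>%
    left_join(totals, by = "tag_id") %>%
    mutate(di = if_else(.data$tot_dets > 0 & .data$tot_days > 0,
                        (.data$n_detections / .data$tot_dets) *
                          (.data$n_detection_days / .data$tot_days),
                        0)) %>%
    group_by(.data$tag_id) %>%
    mutate(
      sfi = if (sum(.data$di) > 0) 100 * .data$di / sum(.data$di) else NA_real_,
      rank = if (sum(.data$di) > 0) {
        sfi_rank(.data$di, .data$station_id)
      } else NA_integer_
    ) %>%
    ungroup() %>%
    select("tag_id", "station_id", "n_detections", "n_detection_days",
           "di", "sfi", "rank")
  usage
}

# ranks 1..k by descending di, ties broken by station id (lexical)
sfi_rank <- function(di, station_id) {
  r <- integer(length(di))
  r[order(-di, station_id)] <- seq_along(di)
  r
}

#' Minimum linear displacement
#'
#' A shark's linear home-range proxy: the great-circle distance between the
#' two most distant stations that detected it, plus 0.6 km (twice the 0.3 km
#' detection radius, assuming the animal sat on the outer edge of each
#' detection circle). A shark heard on a single station gets the distance
#' from its tagging location to that station plus a single 0.3 km radius.
#' Also counts the islands visited and flags long-distance movers
#' (MLD > 50 km).
#'
#' @param dets Pre-processed detections.
#' @param sharks Shark metadata (`tag_id`, `tagging_lat`, `tagging_lon`).
#' @param stations Station table.
#' @param detection_radius_km Receiver detection radius (default 0.3).
#' @return Tibble `tag_id`, `mld_km`, `endpoint_a`, `endpoint_b`,
#'   `n_islands`, `long_distance`; sharks without detections are absent.
#' @export
minimum_linear_displacement <- function(dets, sharks, stations,
                                        detection_radius_km = 0.3) {
  stations <- validate_stations(stations)
  per_shark <- dets %>%
    distinct(.data$tag_id, .data$station_id) %>%
    left_join(select(stations, "station_id", "island", "lat", "lon"),
              by = "station_id")
  if (anyNA(per_shark$lat)) abort("Detections reference stations missing coordinates.")

  one <- function(df, tag) {
    k <- nrow(df)
    if (k == 1L) {
      sh <- sharks[sharks$tag_id == tag, ]
      if (nrow(sh) == 0 || anyNA(c(sh$tagging_lat, sh$tagging_lon))) {
        abort(paste0("Single-station shark ", tag, " needs a tagging location."))
      }
      d <- great_circle_km(sh$tagging_lat, sh$tagging_lon, df$lat, df$lon)
      tibble(mld_km = d + detection_radius_km,
             endpoint_a = "tagging-location", endpoint_b = df$station_id)
    } else {
      pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
      d <- great_circle_km(df$lat[pairs[, 1]], df$lon[pairs[, 1]],
                           df$lat[pairs[, 2]], df$lon[pairs[, 2]])
      best <- which.max(d)
      tibble(mld_km = d[best] + 2 * detection_radius_km,
             endpoint_a = df$station_id[pairs[best, 1]],
             endpoint_b = df$station_id[pairs[best, 2]])
    }
  }
  per_shark %>%
    group_by(.data$tag_id) %>%
    dplyr::group_modify(~ mutate(one(.x, .y$tag_id), n_islands = n_distinct(.x$island))) %>%
    ungroup() %>%
    mutate(long_distance = .data$mld_km > 50)
}

#' Station Utilization Index
#'
#' Ranks receiver stations by combined use: the proportion of all detected
#' sharks that visited the station times its "Station Days" (station
#' detection days over working days) normalised by the array-wide total of
#' detection days,
#' `UI = (sharks at station / sharks detected in array) x
#'  (station days / total detection days in array)`.
#' The index mixes a ratio with a count and is dimensionally idiosyncratic;
#' its absolute magnitude is not comparable across studies and it is used
#' only to rank stations ("hotspots").
#'
#' @param dets Pre-processed detections.
#' @param working_days Output of [station_working_days()] (stations with
#'   zero or unknown working days are excluded with a warning).
#' @param config A [study_config()].
#' @return Tibble `station_id`, `island`, `working_days`, `n_detection_days`,
#'   `station_days`, `n_sharks`, `ui`, sorted by descending `ui`.
#' @export
utilization_index <- function(dets, working_days, config) {
  tot_sharks <- n_distinct(dets$tag_id)
  tot_days <- dets %>%
    count(.data$tag_id, .data$date_local, name = "n_day") %>%
    summarise(d = sum(.data$n_day >= 2L)) %>%
    pull(.data$d)

  st <- dets %>%
    count(.data$tag_id, .data$station_id, .data$date_local, name = "n_day") %>%
    group_by(.data$station_id) %>%
    summarise(
      n_detection_days = sum(.data$n_day >= config$station_day_min_detections),
      n_sharks = n_distinct(.data$tag_id[.data$n_day >= config$station_day_min_detections]),
      .groups = "drop"
    )
  island <- distinct(dets, .data$station_id, .data$island)

  out <- working_days %>%
    filter(!.data$excluded) %>%
    left_join(st, by = "station_id") %>%
    left_join(island, by = "station_id") %>%
    mutate(
      n_detection_days = dplyr::coalesce(.data$n_detection_days, 0L),
      n_sharks = dplyr::coalesce(.data$n_sharks, 0L)
    )
  bad <- out$working_days <= 0
  if (any(bad)) {
    warn(sprintf("Excluding %d station(s) with zero working days.", sum(bad)))
    out <- out[!bad, ]
  }
  out %>%
    mutate(
      station_days = .data$n_detection_days / .data$working_days,
      ui = if (tot_sharks > 0 && tot_days > 0) {
        (.data$n_sharks / tot_sharks) * (.data$station_days / tot_days)
      } else 0
    ) %>%
    select("station_id", "island", "working_days", "n_detection_days",
           "station_days", "n_sharks", "ui") %>%
    arrange(dplyr::desc(.data$ui))
}

#' Monthly Activity Index
#'
#' Seasonal activity profile over the twelve calendar months, aggregated
#' across years: the proportion of detection days (shark-days with >= 2
#' detections in that month over the summed working days of all stations in
#' that month) times the proportion of sharks (distinct sharks detected
#' that month over all detected sharks),
#' `AI = prop_detection_days x prop_sharks`.
#' Months in which no station was working are reported with `NA`.
#'
#' @param dets Pre-processed detections.
#' @param deployments Deployment calendar (for per-month working days).
#' @param config A [study_config()].
#' @return Tibble `month`, `working_days`, `n_detection_days`, `n_sharks`,
#'   `prop_detection_days`, `prop_sharks`, `ai`.
#' @export
activity_index <- function(dets, deployments, config) {
  deployments <- validate_deployments(deployments)
  # working days of all stations, by calendar month across years
  days <- deployments %>%
    mutate(
      from = pmax(.data$start_date, config$study_start),
      to = pmin(if_else(is.na(.data$end_date), config$study_end, .data$end_date),
                config$study_end)
    ) %>%
    filter(.data$from <= .data$to)
  all_days <- purrr::pmap(list(days$station_id, days$from, days$to),
                          function(s, f, t) tibble(station_id = s,
                                                   day = seq(f, t, by = "day")))
  wd_month <- bind_rows(all_days) %>%
    distinct(.data$station_id, .data$day) %>%
    count(month = lubridate::month(.data$day), name = "working_days")

  tot_sharks <- n_distinct(dets$tag_id)
  det_month <- dets %>%
    count(.data$tag_id, .data$date_local, name = "n_day") %>%
    mutate(month = lubridate::month(.data$date_local)) %>%
    group_by(.data$month) %>%
    summarise(
      n_detection_days = sum(.data$n_day >= 2L),
      n_sharks = n_distinct(.data$tag_id[.data$n_day >= 2L]),
      .groups = "drop"
    )

  tibble(month = 1:12) %>%
    left_join(wd_month, by = "month") %>%
    left_join(det_month, by = "month") %>%
    mutate(
      working_days = dplyr::coalesce(.data$working_days, 0L),
      n_detection_days = dplyr::coalesce(.data$n_detection_days, 0L),
      n_sharks = dplyr::coalesce(.data$n_sharks, 0L),
      prop_detection_days = if_else(.data$working_days > 0,
                                    .data$n_detection_days / .data$working_days,
                                    NA_real_),
      prop_sharks = if (tot_sharks > 0) .data$n_sharks / tot_sharks else 0,
      ai = .data$prop_detection_days * .data$prop_sharks
    )
}
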
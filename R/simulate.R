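#' Simulation configuration
#'
#' Parameters of the agent-based detection-log generator. The defaults
#' emulate the study system the package targets: an archipelago array of
#' perimeter receiver stations, coded tags transmitting on a randomised
#' ~90 s delay with a 300 m detection radius, shark total lengths of
#' 76-196 cm with V9 tags below 110 cm (shorter battery) and V16 above,
#' four behavioural archetypes (Resident, Pseudo-resident, Transient,
#' Passer-by), and summer-biased inter-island excursions.
#'
#' Movement is a daily-resolution station Markov chain: each day a shark is
#' either absent (undetectable) or spends a residence window near one
#' station, transmitting at exponentially-spaced intervals, each
#' transmission detected independently with `detection_prob_in_range`.
#'
#' @param islands Tibble with one row per island: `island`, `lat`, `lon`
#'   (centroid), `n_stations`, `radius_km` (perimeter circle).
#' @param n_sharks Number of tagged sharks.
#' @param archetype_mix Named proportions over
#'   `c("Resident","PseudoResident","Transient","PasserBy")`; must sum to 1.
#' @param prop_undetected Fraction of tagged sharks never heard by the
#'   array (tag failure, immediate emigration); their truth archetype is
#'   `"Undetected"`.
#' @param mean_transmission_delay_s Mean of the exponential inter-transmission
#'   delay (default 90 s).
#' @param detection_radius_km Receiver detection radius (default 0.3).
#' @param detection_prob_in_range Per-transmission detection probability
#'   while the shark is within range (default 0.6).
#' @param residence_window_min Minutes per present day spent within range of
#'   the day's station (default 20; with the default delay this yields on
#'   the order of 8 detections per present day).
#' @param swim_speed_bl_per_s Cruising speed in body lengths per second
#'   (default 0.6), used by [crossing_time_s()].
#' @param tl_range_cm Total-length range sampled uniformly (default 76-196).
#' @param tag_life_days Named vector `c(V9 = , V16 = )` of expected battery
#'   life (defaults 480 and 1915 days).
#' @param presence_prob_resident,presence_prob_pseudo Ranges (length-2) from
#'   which a Resident's / Pseudo-resident's daily presence probability is
#'   drawn (defaults 0.35-0.75 and 0.04-0.15).
#' @param home_station_prob Probability that a present day is spent at the
#'   home station rather than a same-island neighbour (default 0.8).
#' @param interisland_trips Mean number of inter-island excursion days per
#'   multi-island-prone shark per year (default 2; only Residents and
#'   Pseudo-residents make excursions).
#' @param summer_interisland_rate_multiplier Weight multiplying summer
#'   months when excursion days are placed (default 6; `Inf` places every
#'   excursion in summer).
#' @param receiver_outage_rate Expected receiver outages per station per
#'   year (default 0.5; mean outage length ~3 weeks).
#' @param noise_detection_rate Expected spurious single detections per
#'   shark-day (default 0.002), emulating code collisions; these are the
#'   records the single-detection filter exists to remove.
#' @param study_span_days Length of the study window (default 1460).
#' @param study_start First day of the study (default `"2010-10-01"`).
#' @param seed Integer RNG seed.
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(islands = NULL,
                       n_sharks = 20L,
                       archetype_mix = c(Resident = 0.18, PseudoResident = 0.15,
                                         Transient = 0.08, PasserBy = 0.59),
                       prop_undetected = 0,
                       mean_transmission_delay_s = 90,
                       detection_radius_km = 0.3,
                       detection_prob_in_range = 0.6,
                       residence_window_min = 20,
                       swim_speed_bl_per_s = 0.6,
                       tl_range_cm = c(76, 196),
                       tag_life_days = c(V9 = 480L, V16 = 1915L),
                       presence_prob_resident = c(0.35, 0.75),
                       presence_prob_pseudo = c(0.04, 0.15),
                       home_station_prob = 0.8,
                       interisland_trips = 2,
                       summer_interisland_rate_multiplier = 6,
                       receiver_outage_rate = 0.5,
                       noise_detection_rate = 0.002,
                       study_span_days = 1460L,
                       study_start = "2010-10-01",
                       seed = 1L) {
  if (is.null(islands)) {
    islands <- tibble(
      island = c("GC", "LC", "CB"),
      lat = c(19.3222, 19.6897, 19.7235),
      lon = c(-81.2409, -80.0367, -79.8017),
      n_stations = c(21L, 28L, 8L),
      radius_km = c(10, 6, 5)
    )
  }
  if (abs(sum(archetype_mix) - 1) > 1e-8) abort("archetype_mix must sum to 1.")
  if (mean_transmission_delay_s <= 0) abort("Transmission delay must be positive.")
  if (detection_prob_in_range <= 0 || detection_prob_in_range > 1) {
    abort("detection_prob_in_range must be in (0, 1].")
  }
  structure(list(
    islands = islands, n_sharks = as.integer(n_sharks),
    archetype_mix = archetype_mix, prop_undetected = prop_undetected,
    mean_transmission_delay_s = mean_transmission_delay_s,
    detection_radius_km = detection_radius_km,
    detection_prob_in_range = detection_prob_in_range,
    residence_window_min = residence_window_min,
    swim_speed_bl_per_s = swim_speed_bl_per_s,
    tl_range_cm = tl_range_cm, tag_life_days = tag_life_days,
    presence_prob_resident = presence_prob_resident,
    presence_prob_pseudo = presence_prob_pseudo,
    home_station_prob = home_station_prob,
    interisland_trips = interisland_trips,
    summer_interisland_rate_multiplier = summer_interisland_rate_multiplier,
    receiver_outage_rate = receiver_outage_rate,
    noise_detection_rate = noise_detection_rate,
    study_span_days = as.integer(study_span_days),
    study_start = as.Date(study_start),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Scenario presets
#'
#' `"cayman-like"`: three islands, 47 + 10 perimeter stations, 66 tagged
#' sharks with the detected-cohort archetype composition and a 27/66
#' never-detected fraction, multi-year span. `"minimal"`: one island, 8
#' stations, 5 sharks, one year - small enough for quick examples.
#'
#' @param name `"cayman-like"` or `"minimal"`.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_scenario <- function(name = c("cayman-like", "minimal"), ...) {
  name <- match.arg(name)
  base <- if (name == "cayman-like") {
    list(n_sharks = 66L, prop_undetected = 27 / 66, study_span_days = 2555L)
  } else {
    list(
      islands = tibble(island = "I1", lat = 19.5, lon = -80.5,
                       n_stations = 8L, radius_km = 5),
      n_sharks = 5L, study_span_days = 365L
    )
  }
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Generate a synthetic receiver array
#'
#' Places each island's stations at equal angles on a perimeter circle
#' around its centroid and builds a deployment calendar for the study
#' window, with random receiver outages (Poisson number per station at
#' `receiver_outage_rate` per year, exponential ~3-week length) splitting
#' deployments into intervals. Deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @return List of tibbles `stations` (`station_id`, `island`, `lat`,
#'   `lon`) and `deployments` (`receiver_serial`, `station_id`,
#'   `start_date`, `end_date`).
#' @export
generate_array <- function(cfg, seed = cfg$seed) {
  if (sum(cfg$islands$n_stations) == 0) abort("Array needs at least one station.")
  set.seed(seed)
  stations <- purrr::pmap(cfg$islands, function(island, lat, lon, n_stations, radius_km) {
    ang <- seq(0, 2 * pi, length.out = n_stations + 1)[seq_len(n_stations)]
    tibble(
      station_id = sprintf("%s%02d", island, seq_len(n_stations)),
      island = island,
      lat = lat + radius_km * sin(ang) / 111.32,
      lon = lon + radius_km * cos(ang) / (111.32 * cos(lat * pi / 180))
    )
  }) %>% bind_rows()

  study_end <- cfg$study_start + cfg$study_span_days - 1
  deployments <- purrr::imap(stations$station_id, function(sid, i) {
    serial <- sprintf("%d", 123000L + i)
    n_out <- rpois(1, cfg$receiver_outage_rate * cfg$study_span_days / 365)
    if (n_out == 0) {
      return(tibble(receiver_serial = serial, station_id = sid,
                    start_date = cfg$study_start, end_date = study_end))
    }
    out_start <- sort(sample.int(cfg$study_span_days, n_out))
    out_len <- pmax(3, round(rexp(n_out, 1 / 18)))
    covered <- rep(TRUE, cfg$study_span_days)
    for (k in seq_len(n_out)) {
      covered[seq(out_start[k], min(cfg$study_span_days, out_start[k] + out_len[k]))] <- FALSE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    up <- which(r$values)
    tibble(receiver_serial = serial, station_id = sid,
           start_date = cfg$study_start + starts[up] - 1,
           end_date = cfg$study_start + ends[up] - 1)
  }) %>% bind_rows()

  list(stations = stations, deployments = deployments)
}

#' Crossing time of a receiver's detection area
#'
#' Seconds a fish of given total length needs, at a cruising speed
#' expressed in body lengths per second, to swim a given distance - e.g.
#' the 600 m diameter of a receiver's detection circle. A 150 cm animal at
#' 0.6 BL/s needs ~667 s for 600 m, several times the nominal transmission
#' delay, which is why per-day presence is reliably detected.
#'
#' @param tl_cm Total length in cm.
#' @param distance_m Distance in metres.
#' @param speed_bl_per_s Speed in body lengths per second.
#' @return Seconds (vectorised).
#' @examples
#' crossing_time_s(150, 600, 0.6)
#' @export
crossing_time_s <- function(tl_cm, distance_m, speed_bl_per_s = 0.6) {
  if (any(c(tl_cm, distance_m, speed_bl_per_s) <= 0)) {
    abort("All arguments must be positive.")
  }
  distance_m / (speed_bl_per_s * tl_cm / 100)
}

# ---- shark behaviour ------------------------------------------------------

# pick excursion days, summer-biased by the rate multiplier
pick_trip_days <- function(dates, n_trips, mult) {
  if (n_trips == 0 || length(dates) == 0) return(as.Date(character()))
  w <- ifelse(lubridate::month(dates) %in% 4:9,
              if (is.infinite(mult)) 1 else mult,
              if (is.infinite(mult)) 0 else 1)
  if (sum(w) == 0) return(as.Date(character()))
  dates[sample.int(length(dates), min(n_trips, sum(w > 0)), prob = w)]
}

#' Simulate tagged sharks on a synthetic array
#'
#' Agent-based generator of a raw detection log with known ground truth.
#' Per shark and day the animal is present at a station (home-biased
#' same-island kernel, with summer-biased inter-island excursion days for
#' resident-type animals) or absent; on present days transmissions are
#' spaced exponentially (mean `mean_transmission_delay_s`) through a
#' residence window near the station and each is detected with
#' `detection_prob_in_range`, provided the station's receiver is deployed
#' that day. Archetype rules shape the presence series: Passer-bys depart
#' for good within 30 days of tagging, Transients surface in two short
#' bursts separated by a > 30-day gap, Residents and Pseudo-residents are
#' present throughout tag life at high respectively low daily probability.
#' Rare spurious single detections are sprinkled in at
#' `noise_detection_rate`. A `prop_undetected` fraction of tags is never
#' heard.
#'
#' @param cfg A [sim_config()].
#' @param array Output of [generate_array()] (generated from `cfg` if
#'   missing).
#' @param seed Seed (defaults to `cfg$seed + 1`, so the array and the
#'   behaviour draw from distinct streams).
#' @return List with class `"sim_output"`: `detections` (raw, VUE-dialect
#'   columns `timestamp_utc`, `receiver_serial`, `tag_id`), `stations`,
#'   `deployments`, `sharks` (metadata table), `truth` (per-tag archetype,
#'   home station, daily presence probability, departure day, trip days),
#'   and `config` (a matching [study_config()]).
#' @export
simulate_sharks <- function(cfg, array = generate_array(cfg), seed = cfg$seed + 1L) {
  stations <- array$stations # force the array before reseeding
  deployments <- array$deployments
  set.seed(seed)
  study_end <- cfg$study_start + cfg$study_span_days - 1
  utc_offset <- -5L

  # station availability lookup: receiver working that local day
  dep_days <- purrr::pmap(deployments, function(receiver_serial, station_id,
                                                start_date, end_date) {
    tibble(station_id = station_id,
           day = seq(start_date, end_date, by = "day"))
  }) %>% bind_rows() %>% mutate(on = TRUE)

  # nearest same-island neighbours for the movement kernel
  neighbours <- function(sid) {
    isl <- stations$island[stations$station_id == sid]
    same <- stations[stations$island == isl & stations$station_id != sid, ]
    if (nrow(same) == 0) return(sid)
    here <- stations[stations$station_id == sid, ]
    d <- great_circle_km(here$lat, here$lon, same$lat, same$lon)
    same$station_id[order(d)][seq_len(min(2, nrow(same)))]
  }

  arch_names <- c("Resident", "PseudoResident", "Transient", "PasserBy")
  n <- cfg$n_sharks
  tag_id <- sprintf("%d", 60000L + seq_len(n))
  tl <- round(runif(n, cfg$tl_range_cm[1], cfg$tl_range_cm[2]))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(17, 22))
  maturity <- if_else(tl >= if_else(sex == "F", 180, 150), "M", "IM")
  tag_type <- if_else(tl < 110, "V9", "V16")
  tag_life <- unname(cfg$tag_life_days[tag_type])
  tagging_date <- cfg$study_start +
    sample.int(max(1L, round(cfg$study_span_days * 0.6)), n, replace = TRUE) - 1L
  isl_prob <- if (nrow(cfg$islands) == 3) c(0.26, 0.60, 0.14) else cfg$islands$n_stations
  tagging_island <- sample(cfg$islands$island, n, replace = TRUE, prob = isl_prob)
  undetected <- runif(n) < cfg$prop_undetected
  archetype <- if_else(undetected, "Undetected",
                       sample(arch_names, n, replace = TRUE,
                              prob = cfg$archetype_mix[arch_names]))

  sim_one <- function(i) {
    isl <- tagging_island[i]
    cand <- stations$station_id[stations$island == isl]
    home <- sample(cand, 1)
    horizon <- min(tag_life[i], as.integer(study_end - tagging_date[i]))
    if (horizon < 1) horizon <- 1L
    days <- tagging_date[i] + seq_len(horizon) - 1L
    presence_prob <- NA_real_
    departure_day <- NA_integer_
    present <- rep(FALSE, horizon)
    arch <- archetype[i]
    if (arch == "Resident") {
      presence_prob <- runif(1, cfg$presence_prob_resident[1], cfg$presence_prob_resident[2])
      present <- runif(horizon) < presence_prob
      present[1] <- TRUE
    } else if (arch == "PseudoResident") {
      presence_prob <- runif(1, cfg$presence_prob_pseudo[1], cfg$presence_prob_pseudo[2])
      present <- runif(horizon) < presence_prob
      present[1] <- TRUE
    } else if (arch == "PasserBy") {
      departure_day <- sample(5:28, 1)
      presence_prob <- 0.8
      idx <- seq_len(min(departure_day, horizon))
      present[idx] <- runif(length(idx)) < presence_prob
      present[1] <- TRUE
    } else if (arch == "Transient") {
      presence_prob <- 0.8
      # burst 1 just after tagging, burst 2 after a > month gap; each burst
      # confined to one calendar month so total detection months stay < 3
      b1 <- seq_len(min(sample(3:6, 1), horizon))
      present[b1] <- runif(length(b1)) < presence_prob
      present[1] <- TRUE
      if (horizon > 70) {
        start2 <- sample(60:min(horizon - 6, 330), 1)
        len2 <- sample(3:6, 1)
        d2 <- days[start2]
        # shift the burst start so it does not straddle a month boundary
        if (lubridate::mday(d2) + len2 > lubridate::days_in_month(d2)) {
          start2 <- start2 - (lubridate::mday(d2) + len2 -
                                lubridate::days_in_month(d2))
        }
        b2 <- seq(start2, min(start2 + len2 - 1, horizon))
        present[b2] <- TRUE
      }
    } # Undetected: all FALSE

    pres_days <- days[present]
    if (length(pres_days) == 0 && arch != "Undetected") pres_days <- days[1]
    n_pres <- length(pres_days)
    if (n_pres == 0) {
      return(list(det = NULL,
                  truth = tibble(tag_id = tag_id[i], archetype = arch,
                                 home_station = home,
                                 daily_presence_prob = presence_prob,
                                 departure_day = departure_day,
                                 n_trip_days = 0L)))
    }

    # station of each present day
    nb <- neighbours(home)
    st <- if_else(runif(n_pres) < cfg$home_station_prob, home,
                  sample(nb, n_pres, replace = TRUE))
    trip_days <- as.Date(character())
    if (arch %in% c("Resident", "PseudoResident") && nrow(cfg$islands) > 1 &&
        cfg$interisland_trips > 0) {
      n_trips <- rpois(1, cfg$interisland_trips * horizon / 365)
      trip_days <- pick_trip_days(pres_days, n_trips,
                                  cfg$summer_interisland_rate_multiplier)
      if (length(trip_days) > 0) {
        away <- stations$station_id[stations$island != isl]
        st[pres_days %in% trip_days] <- sample(away, length(trip_days),
                                               replace = TRUE)
      }
    }

    # detections within the day's residence window
    lambda <- cfg$residence_window_min * 60 / cfg$mean_transmission_delay_s
    n_det <- rbinom(n_pres, rpois(n_pres, lambda), cfg$detection_prob_in_range)
    keep <- n_det > 0
    det <- NULL
    if (any(keep)) {
      win_start <- runif(sum(keep), 0, 24 * 3600 - cfg$residence_window_min * 60)
      det <- tibble(
        day = rep(pres_days[keep], n_det[keep]),
        station_id = rep(st[keep], n_det[keep]),
        secs = rep(win_start, n_det[keep]) +
          runif(sum(n_det[keep]), 0, cfg$residence_window_min * 60)
      ) %>%
        # receiver must be working that day
        inner_join(dep_days, by = c("station_id", "day" = "day")) %>%
        mutate(tag_id = tag_id[i],
               timestamp_local = as.POSIXct(.data$day, tz = "UTC") + .data$secs) %>%
        select("tag_id", "station_id", "timestamp_local")
    }
    list(det = det,
         truth = tibble(tag_id = tag_id[i], archetype = arch, home_station = home,
                        daily_presence_prob = presence_prob,
                        departure_day = departure_day,
                        n_trip_days = length(trip_days)))
  }

  sims <- purrr::map(seq_len(n), sim_one)
  det <- bind_rows(purrr::map(sims, "det"))
  truth <- bind_rows(purrr::map(sims, "truth"))

  # spurious single detections: random tag at a random working station
  n_noise <- rpois(1, cfg$noise_detection_rate * n * cfg$study_span_days)
  if (n_noise > 0 && nrow(dep_days) > 0) {
    pick <- dep_days[sample.int(nrow(dep_days), n_noise, replace = TRUE), ]
    noise <- tibble(
      tag_id = sample(tag_id, n_noise, replace = TRUE),
      station_id = pick$station_id,
      timestamp_local = as.POSIXct(pick$day, tz = "UTC") + runif(n_noise, 0, 86399)
    ) %>%
      # a code collision can only mimic a tag already in the water
      filter(as.Date(.data$timestamp_local, tz = "UTC") >=
               tagging_date[match(.data$tag_id, .env$tag_id)])
    det <- bind_rows(det, noise)
  }

  serial_of <- setNames(deployments$receiver_serial[!duplicated(deployments$station_id)],
                        deployments$station_id[!duplicated(deployments$station_id)])
  detections <- det %>%
    mutate(timestamp_utc = .data$timestamp_local - utc_offset * 3600,
           receiver_serial = unname(serial_of[.data$station_id])) %>%
    select("timestamp_utc", "receiver_serial", "tag_id") %>%
    arrange(.data$timestamp_utc, .data$receiver_serial, .data$tag_id)

  sharks <- tibble(
    tag_id = tag_id, sex = sex, maturity = maturity, tl_cm = tl,
    tagging_date = tagging_date,
    tagging_lat = stations$lat[match(truth$home_station, stations$station_id)] + 0.002,
    tagging_lon = stations$lon[match(truth$home_station, stations$station_id)] + 0.002,
    island = tagging_island, tag_type = tag_type, tag_life_days = tag_life
  )

  structure(list(
    detections = detections, stations = stations, deployments = deployments,
    sharks = sharks, truth = truth,
    config = study_config(cfg$study_start, study_end,
                          utc_offset_hours = utc_offset, rng_seed = seed)
  ), class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("<sim_output>\n")
  cat(sprintf("  %d raw detections, %d sharks (%d detected), %d stations\n",
              nrow(x$detections), nrow(x$sharks),
              dplyr::n_distinct(x$detections$tag_id), nrow(x$stations)))
  print(table(x$truth$archetype))
  invisible(x)
}

#' Write a simulated scenario to the pipeline's input CSVs
#'
#' Emits the four input files the pipeline consumes - detections in the
#' receiver-download dialect (`Date and Time (UTC)`, `Receiver`,
#' `Transmitter`), stations, deployments, sharks - plus `truth.csv` with
#' the generating parameters per tag.
#'
#' @param sim A `sim_output`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_csvs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vue <- tibble(
    `Date and Time (UTC)` = format(sim$detections$timestamp_utc, "%Y-%m-%d %H:%M:%S"),
    Receiver = paste0("VR2W-", sim$detections$receiver_serial),
    Transmitter = paste0("A69-1602-", sim$detections$tag_id)
  )
  readr::write_csv(vue, file.path(dir, "detections.csv"))
  readr::write_csv(sim$stations, file.path(dir, "stations.csv"))
  readr::write_csv(sim$deployments, file.path(dir, "deployments.csv"))
  readr::write_csv(sim$sharks, file.path(dir, "sharks.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
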
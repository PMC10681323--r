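#' Run the full telemetry analysis pipeline
#'
#' End-to-end driver: pre-processes a raw detection log (station-calendar
#' resolution, duplicate and single-detection removal, exclusion of
#' under-deployed stations), then computes every per-shark and per-station
#' product: detection metrics, Residency Index and residency class, station
#' usage with Detection/Site-Fidelity indices, minimum linear displacement,
#' station Utilization Index, monthly Activity Index, and the season/diel
#' movement networks. Deterministic given the inputs and
#' `config$rng_seed`.
#'
#' @param raw Raw detections (tibble from [read_detections()] or the
#'   simulator) or a path to a detection CSV.
#' @param stations,deployments,sharks Metadata tibbles or CSV paths.
#' @param config A [study_config()].
#' @return A list with class `"reef_analysis"`: `per_shark` (the
#'   Table-2-style summary), `cohort` (one-row cohort statistics),
#'   `station_usage`, `utilization`, `activity`, `networks` (season and
#'   diel `movement_network`s), `working_days`, `counts`, `detections`
#'   (the analysis-ready detection tibble) and `config`.
#' @export
run_pipeline <- function(raw, stations, deployments, sharks, config) {
  if (is.character(raw)) raw <- read_detections(raw, config)
  if (is.character(stations)) stations <- read_stations(stations)
  if (is.character(deployments)) deployments <- read_deployments(deployments)
  if (is.character(sharks)) sharks <- read_sharks(sharks)
  sharks <- validate_sharks(sharks)

  pre <- preprocess_detections(raw, deployments, stations, config)
  dets <- semi_join(pre$detections, sharks, by = "tag_id")

  metrics <- detection_metrics(dets, sharks, config)
  residency <- classify_residency(metrics, config)

  usage <- station_usage(dets, config)
  primary <- usage %>%
    filter(.data$rank == 1L) %>%
    select("tag_id", primary_station = "station_id", sfi_primary = "sfi")
  n_recs <- usage %>% count(.data$tag_id, name = "n_receivers")

  mld <- if (nrow(dets) > 0) {
    minimum_linear_displacement(dets, sharks, stations)
  } else {
    tibble(tag_id = character(), mld_km = numeric(), n_islands = integer(),
           long_distance = logical())
  }

  per_shark <- sharks %>%
    select("tag_id", "sex", "maturity", "tl_cm", "tagging_date", "island",
           "tag_type", "tag_life_days") %>%
    left_join(select(residency, -"tagging_date"), by = "tag_id") %>%
    left_join(n_recs, by = "tag_id") %>%
    left_join(select(mld, "tag_id", "mld_km", "n_islands", "long_distance"),
              by = "tag_id") %>%
    left_join(primary, by = "tag_id") %>%
    mutate(n_receivers = dplyr::coalesce(.data$n_receivers, 0L))

  util <- utilization_index(dets, pre$working_days, config)
  act <- activity_index(dets, deployments, config)

  dp <- assign_period(dets, config)
  nets <- list(
    summer = build_network(filter(dp, .data$season == "summer"), stations, "summer"),
    winter = build_network(filter(dp, .data$season == "winter"), stations, "winter"),
    day = build_network(filter(dp, .data$diel == "day"), stations, "day"),
    night = build_network(filter(dp, .data$diel == "night"), stations, "night")
  )

  structure(list(
    per_shark = per_shark,
    cohort = cohort_summary(per_shark),
    station_usage = usage,
    utilization = util,
    activity = act,
    networks = nets,
    working_days = pre$working_days,
    counts = pre$counts,
    detections = dets,
    config = config
  ), class = "reef_analysis")
}

#' @export
print.reef_analysis <- function(x, ...) {
  cat("<reef_analysis>\n")
  cat(sprintf("  %d tagged sharks, %d detected; %d analysed detections\n",
              nrow(x$per_shark), sum(x$per_shark$n_detections > 0),
              unname(x$counts["analysed"])))
  cat(sprintf("  mean RI %.3f | mean primary SFI %.1f%% | mean MLD %.1f km\n",
              x$cohort$mean_ri,
              mean(x$per_shark$sfi_primary, na.rm = TRUE),
              mean(x$per_shark$mld_km, na.rm = TRUE)))
  print(attr(x$cohort, "cr_counts"))
  invisible(x)
}

#' Tidy the per-shark summary of a pipeline run
#'
#' @param x A `reef_analysis`.
#' @param ... Unused.
#' @return The per-shark summary tibble (one row per tagged shark).
#' @method tidy reef_analysis
#' @export
tidy.reef_analysis <- function(x, ...) x$per_shark

#' One-row cohort summary of a pipeline run
#'
#' @param x A `reef_analysis`.
#' @param ... Unused.
#' @return One-row tibble of cohort statistics.
#' @method glance reef_analysis
#' @export
glance.reef_analysis <- function(x, ...) x$cohort

#' Write the pipeline products to CSV
#'
#' Emits the per-shark summary (Table-2 column order), per-station
#' utilization, monthly activity, and each network's edge list.
#'
#' @param result A `reef_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$per_shark, file.path(dir, "per_shark.csv"))
  readr::write_csv(result$utilization, file.path(dir, "utilization.csv"))
  readr::write_csv(result$activity, file.path(dir, "activity.csv"))
  readr::write_csv(result$station_usage, file.path(dir, "station_usage.csv"))
  for (nm in names(result$networks)) {
    export_network(result$networks[[nm]], file.path(dir, paste0("network_", nm, ".csv")))
  }
  invisible(dir)
}
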
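#' Plot the monthly Activity Index
#'
#' Bar chart of the monthly Activity Index (proportion of detection days
#' times proportion of detected sharks), the standard seasonal-activity
#' display for a telemetry cohort.
#'
#' @param activity Output of [activity_index()] (or
#'   `reef_analysis$activity`).
#' @return A ggplot object.
#' @export
plot_activity <- function(activity) {
  ggplot2::ggplot(activity,
                  ggplot2::aes(x = factor(.data$month, levels = 1:12,
                                          labels = month.abb),
                               y = .data$ai)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "Activity Index") +
    ggplot2::theme_minimal()
}

#' Plot SFI against distance to the primary receiver
#'
#' Scatter of each receiver's Site-Fidelity Index against its great-circle
#' distance from the shark's primary receiver; a negative trend is the
#' signature of site-fidelity.
#'
#' @param usage Output of [station_usage()].
#' @param stations Station table with coordinates.
#' @return A ggplot object.
#' @export
plot_sfi_distance <- function(usage, stations) {
  stations <- validate_stations(stations)
  prim <- usage %>%
    filter(.data$rank == 1L) %>%
    select("tag_id", primary = "station_id")
  df <- usage %>%
    left_join(prim, by = "tag_id") %>%
    left_join(select(stations, "station_id", "lat", "lon"), by = "station_id") %>%
    left_join(select(stations, primary = "station_id", plat = "lat", plon = "lon"),
              by = "primary") %>%
    mutate(dist_km = great_circle_km(.data$lat, .data$lon, .data$plat, .data$plon))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dist_km, y = .data$sfi)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(x = "Distance to primary receiver (km)",
                  y = "Site-Fidelity Index (%)") +
    ggplot2::theme_minimal()
}

#' Autoplot a movement network
#'
#' Draws the directed movement network with nodes at station coordinates,
#' node size scaled by degree and edge width by movement count.
#'
#' @param object A `movement_network`.
#' @param stations Station table with coordinates.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot movement_network
#' @export
autoplot.movement_network <- function(object, stations, ...) {
  stations <- validate_stations(stations)
  deg <- node_degrees(object) %>%
    left_join(select(stations, "station_id", "lat", "lon"), by = "station_id")
  idx <- which(object$adjacency > 0, arr.ind = TRUE)
  edges <- tibble(
    from = object$nodes[idx[, 1]], to = object$nodes[idx[, 2]],
    weight = object$adjacency[idx]
  ) %>%
    left_join(select(deg, from = "station_id", x = "lon", y = "lat"), by = "from") %>%
    left_join(select(deg, to = "station_id", xend = "lon", yend = "lat"), by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   linewidth = .data$weight),
      colour = "grey55",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(data = deg,
                        ggplot2::aes(x = .data$lon, y = .data$lat,
                                     size = .data$degree)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::labs(x = "Longitude", y = "Latitude", title = object$label) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
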
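#' Assign season and diel period to detections
#'
#' Labels each detection with its season (summer/winter by calendar month of
#' the local date) and diel period (day/night by local clock time, inclusive
#' bounds: with the defaults, 06:30:00 is day and 18:30:00 is night).
#'
#' @param dets Resolved detections (`timestamp_local`, `date_local`).
#' @param config A [study_config()].
#' @return `dets` with added factor columns `season` and `diel`.
#' @export
assign_period <- function(dets, config) {
  day_lo <- parse_clock_min(config$day_start)
  day_hi <- parse_clock_min(config$day_end)
  mins <- lubridate::hour(dets$timestamp_local) * 60L +
    lubridate::minute(dets$timestamp_local)
  mutate(dets,
    season = factor(if_else(lubridate::month(.data$date_local) %in% config$summer_months,
                            "summer", "winter"), levels = c("summer", "winter")),
    diel = factor(if_else(mins >= day_lo & mins <= day_hi, "day", "night"),
                  levels = c("day", "night"))
  )
}

#' Build a directed movement network
#'
#' Constructs the station-by-station adjacency matrix of successive
#' detections: for each shark, every consecutive pair of detections at
#' *distinct* stations adds one movement to `adjacency[from, to]`.
#' Consecutive detections at the same station collapse (no self-loops).
#' When the detections were filtered to a subset (a sex, a season, a diel
#' period), pairing happens within the subset, so an edge links each
#' detection to the previous subset detection of the same shark.
#'
#' @param dets Detections for the subset, any order (sorted internally per
#'   shark by time).
#' @param stations Station table defining the node universe (all stations
#'   appear as nodes, connected or not).
#' @param label Optional subset descriptor stored on the network.
#' @param max_gap_days Optional maximum time between consecutive detections
#'   for them to count as a movement; default `Inf` (no cutoff).
#' @return A `movement_network`: list with `nodes`, `adjacency` (integer
#'   matrix), `label`.
#' @export
build_network <- function(dets, stations, label = NULL, max_gap_days = Inf) {
  stations <- validate_stations(stations)
  nodes <- sort(stations$station_id)
  unknown <- setdiff(unique(dets$station_id), nodes)
  if (length(unknown) > 0) {
    abort(paste0("Detections reference unknown station(s): ",
                 paste(unknown, collapse = ", ")))
  }
  adj <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(dets) > 0) {
    moves <- dets %>%
      arrange(.data$tag_id, .data$timestamp_local) %>%
      group_by(.data$tag_id) %>%
      mutate(
        from = lag(.data$station_id),
        gap_days = as.numeric(difftime(.data$timestamp_local,
                                       lag(.data$timestamp_local), units = "days"))
      ) %>%
      ungroup() %>%
      filter(!is.na(.data$from), .data$from != .data$station_id,
             .data$gap_days <= max_gap_days) %>%
      count(.data$from, to = .data$station_id)
    if (nrow(moves) > 0) {
      adj[cbind(moves$from, moves$to)] <- moves$n
    }
  }
  structure(list(nodes = nodes, adjacency = adj, label = label),
            class = "movement_network")
}

#' @export
print.movement_network <- function(x, ...) {
  deg <- node_degrees(x)
  used <- deg$degree[deg$degree > 0]
  cat("<movement_network", if (!is.null(x$label)) paste0(" '", x$label, "'"), ">\n",
      sep = "")
  cat(sprintf("  %d nodes, %d with connections; %d directed edges, %d movements\n",
              length(x$nodes), sum(deg$degree > 0), sum(x$adjacency > 0),
              sum(x$adjacency)))
  if (length(used)) {
    cat(sprintf("  node degrees %d-%d; edge weights %d-%d\n",
                min(used), max(used),
                min(x$adjacency[x$adjacency > 0]), max(x$adjacency)))
  }
  invisible(x)
}

#' Node degrees of a movement network
#'
#' Degree of a station = number of distinct stations it received movements
#' from plus number of distinct stations it sent movements to (in- plus
#' out-neighbour counts on the directed network); a proxy for the traffic
#' through a receiver.
#'
#' @param net A `movement_network`.
#' @return Tibble `station_id`, `in_neighbours`, `out_neighbours`, `degree`.
#' @export
node_degrees <- function(net) {
  a <- net$adjacency > 0
  tibble(
    station_id = net$nodes,
    in_neighbours = unname(colSums(a)),
    out_neighbours = unname(rowSums(a)),
    degree = unname(colSums(a) + rowSums(a))
  )
}

#' Network summary in figure-caption style
#'
#' @param net A `movement_network`.
#' @return One-row tibble: node/edge counts, degree range, weight range.
#' @export
network_summary <- function(net) {
  deg <- node_degrees(net)$degree
  w <- net$adjacency[net$adjacency > 0]
  tibble(
    label = net$label %||% NA_character_,
    n_nodes = length(net$nodes),
    n_connected_nodes = sum(deg > 0),
    n_edges = sum(net$adjacency > 0),
    n_movements = sum(net$adjacency),
    degree_min = if (length(w)) min(deg[deg > 0]) else NA_integer_,
    degree_max = if (length(w)) max(deg) else NA_integer_,
    weight_min = if (length(w)) min(w) else NA_integer_,
    weight_max = if (length(w)) max(w) else NA_integer_
  )
}

#' Mantel permutation test for matrix overlap
#'
#' Correlates two equally-labelled square matrices (e.g. the adjacency
#' matrices of two group-specific movement networks) by the Pearson
#' correlation of their off-diagonal entries, and assesses it against the
#' null distribution generated by simultaneous row-and-column permutation
#' of the second matrix. The upper-tail p-value uses the add-one rule,
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`, so `p >= 1/(n_perm + 1)`.
#'
#' @param m1,m2 Square numeric matrices of equal dimension and node order.
#' @param n_perm Number of permutations (>= 99; default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param tail `"greater"` (default), `"less"` or `"two.sided"`.
#' @return Tibble `method`, `statistic` (r), `p_value`, `n_perm`, `seed`.
#' @export
mantel_test <- function(m1, m2, n_perm = 9999, seed = 1L, tail = "greater") {
  if (!all(dim(m1) == dim(m2)) || nrow(m1) != ncol(m1)) {
    abort("Matrices must be square and of equal size.")
  }
  if (n_perm < 99) abort("Use at least 99 permutations.")
  tail <- match.arg(tail, c("greater", "less", "two.sided"))
  off <- !diag(TRUE, nrow(m1))
  x <- m1[off]
  if (stats::sd(x) == 0 || stats::sd(m2[off]) == 0) {
    abort("Mantel r is undefined for a zero-variance matrix.")
  }
  r_obs <- cor(x, m2[off])
  set.seed(seed)
  n <- nrow(m1)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(x, m2[p, p][off])
  }, numeric(1))
  exceed <- switch(tail,
    greater = sum(r_perm >= r_obs),
    less = sum(r_perm <= r_obs),
    two.sided = sum(abs(r_perm) >= abs(r_obs))
  )
  tibble(method = "Mantel permutation test", statistic = r_obs,
         p_value = (1 + exceed) / (1 + n_perm),
         n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Compare mobility between two networks
#'
#' Rank test (Mann-Whitney) on the node-degree vectors of two movement
#' networks built over the same station universe; by default only stations
#' with a connection in at least one of the two groups enter (otherwise the
#' many never-connected stations swamp the comparison with zeros).
#'
#' @param net_a,net_b `movement_network`s over identical nodes.
#' @param include_all_nodes Keep degree-0-in-both stations (default FALSE).
#' @return Tibble as returned by [mann_whitney_u()].
#' @export
compare_mobility <- function(net_a, net_b, include_all_nodes = FALSE) {
  if (!identical(net_a$nodes, net_b$nodes)) {
    abort("Networks must share the same station universe.")
  }
  da <- node_degrees(net_a)$degree
  db <- node_degrees(net_b)$degree
  if (!include_all_nodes) {
    keep <- da > 0 | db > 0
    if (!any(keep)) abort("Both networks are empty; no degrees to compare.")
    da <- da[keep]
    db <- db[keep]
  }
  mann_whitney_u(da, db)
}

#' Export a movement network
#'
#' Writes the edge list as CSV (`from,to,weight`; header-only for an empty
#' network) and, optionally, GraphML with island and degree node
#' attributes, readable by standard graph software.
#'
#' @param net A `movement_network`.
#' @param path Output path; `.csv` gets the edge list, `.graphml` the
#'   GraphML document.
#' @param stations Station table (island attribute for GraphML; optional).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, stations = NULL) {
  edges <- which(net$adjacency > 0, arr.ind = TRUE)
  el <- tibble(
    from = net$nodes[edges[, 1]],
    to = net$nodes[edges[, 2]],
    weight = net$adjacency[edges]
  ) %>% arrange(.data$from, .data$to)
  if (grepl("\\.graphml$", path)) {
    g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "directed",
                                             weighted = TRUE)
    igraph::V(g)$degree <- node_degrees(net)$degree
    if (!is.null(stations)) {
      igraph::V(g)$island <- stations$island[match(net$nodes, stations$station_id)]
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_csv(el, path)
  }
  invisible(path)
}

#' Read a movement network back from an exported file
#'
#' Round-trip companion of [export_network()]: rebuilds the adjacency
#' matrix from an edge-list CSV or a GraphML file.
#'
#' @param path File written by [export_network()].
#' @param nodes Station universe for the rebuilt matrix (defaults to the
#'   nodes present in the file).
#' @return A `movement_network`.
#' @export
read_network <- function(path, nodes = NULL) {
  if (grepl("\\.graphml$", path)) {
    g <- igraph::read_graph(path, format = "graphml")
    adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE))
    nodes <- nodes %||% sort(rownames(adj))
    full <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    full[rownames(adj), colnames(adj)] <- as.integer(adj)
  } else {
    el <- readr::read_csv(path, col_types = "cci", progress = FALSE)
    nodes <- nodes %||% sort(unique(c(el$from, el$to)))
    full <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    if (nrow(el) > 0) full[cbind(el$from, el$to)] <- el$weight
  }
  structure(list(nodes = nodes, adjacency = full, label = NULL),
            class = "movement_network")
}
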
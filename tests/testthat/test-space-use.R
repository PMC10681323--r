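test_that("great-circle distance matches closed forms and a geodesic reference", {
  expect_equal(great_circle_km(19.3, -81.2, 19.3, -81.2), 0)
  # antipodal points: half the sphere circumference
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-10)
  # independent reference implementation on the same sphere
  ref <- geosphere::distHaversine(c(-81.2409, 19.3222), c(-79.8017, 19.7235),
                                  r = 6371000) / 1000
  got <- great_circle_km(19.3222, -81.2409, 19.7235, -79.8017)
  expect_lt(abs(got - ref) / ref, 0.001)
  expect_error(great_circle_km(95, 0, 0, 0), "Coordinates")
})

test_that("great-circle distance is symmetric and satisfies the triangle inequality", {
  set.seed(21)
  for (i in 1:25) {
    p <- matrix(c(runif(3, -60, 60), runif(3, -179, 179)), ncol = 2)
    d_ab <- great_circle_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d_ba <- great_circle_km(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    d_bc <- great_circle_km(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    d_ac <- great_circle_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_equal(d_ab, d_ba)
    expect_lte(d_ac, d_ab + d_bc + 1e-9)
  }
})

test_that("detection and site-fidelity indices follow the product and normalization rules", {
  cfg <- toy_config()
  # single-station shark: DI = 1, SFI = 100, rank 1
  u1 <- station_usage(dplyr::bind_rows(day_of_dets("2015-03-01", "A", "t1", 3),
                                       day_of_dets("2015-03-02", "A", "t1", 2)), cfg)
  expect_equal(u1$di, 1)
  expect_equal(u1$sfi, 100)
  expect_equal(u1$rank, 1L)

  # 50% of detections and 50% of detection days at a station -> DI 0.25
  u2 <- station_usage(dplyr::bind_rows(day_of_dets("2015-03-01", "A", "t1", 4),
                                       day_of_dets("2015-03-02", "B", "t1", 4)), cfg)
  expect_equal(u2$di, c(0.25, 0.25))
  expect_equal(sort(u2$rank), 1:2)
  expect_equal(u2$rank, 1:2) # equal DI: tie broken by station id order

  # three-station fixture against hand arithmetic:
  # A: 6 det / 2 days; B: 3 det / 1 day; C: 1 det / 0 station-days
  dets <- dplyr::bind_rows(
    day_of_dets("2015-03-01", "A", "t1", 3),
    day_of_dets("2015-03-02", "A", "t1", 3),
    day_of_dets("2015-03-03", "B", "t1", 3),
    loc_det("2015-03-03 15:00:00", "C", "t1", island = "I2")
  )
  u3 <- station_usage(dets, cfg)
  # shark totals: 10 detections, 3 array-wide detection days
  di_a <- (6 / 10) * (2 / 3)
  di_b <- (3 / 10) * (1 / 3)
  expect_equal(u3$di[u3$station_id == "A"], di_a)
  expect_equal(u3$di[u3$station_id == "B"], di_b)
  expect_equal(u3$di[u3$station_id == "C"], 0)
  expect_equal(u3$sfi[u3$station_id == "A"], 100 * di_a / (di_a + di_b))
  expect_equal(u3$rank[order(u3$station_id)], c(1L, 2L, 3L))
})

test_that("per shark, SFI sums to 100 and the DI total never exceeds 1", {
  cfg <- sim_scenario("minimal", seed = 23, n_sharks = 8L)
  sim <- simulate_sharks(cfg)
  res <- run_pipeline(sim$detections, sim$stations, sim$deployments,
                      sim$sharks, sim$config)
  sums <- res$station_usage |>
    dplyr::filter(!is.na(sfi)) |>
    dplyr::group_by(tag_id) |>
    dplyr::summarise(s = sum(sfi), d = sum(di))
  expect_true(all(abs(sums$s - 100) < 1e-9))
  expect_true(all(sums$d <= 1 + 1e-12))
})

test_that("minimum linear displacement applies the detection-radius corrections", {
  st <- toy_stations()
  shark <- toy_shark("t1")
  # two stations: farthest pair + 2 x 0.3 km
  dets <- dplyr::bind_rows(day_of_dets("2015-03-01", "A", "t1", 2),
                           day_of_dets("2015-03-02", "B", "t1", 2))
  d_ab <- great_circle_km(st$lat[1], st$lon[1], st$lat[2], st$lon[2])
  m <- minimum_linear_displacement(dets, shark, st)
  expect_equal(m$mld_km, d_ab + 0.6)
  expect_equal(m$n_islands, 1L)

  # single station: distance from the tagging location + one radius
  dets1 <- day_of_dets("2015-03-01", "B", "t1", 2)
  d_tag <- great_circle_km(shark$tagging_lat, shark$tagging_lon,
                           st$lat[2], st$lon[2])
  m1 <- minimum_linear_displacement(dets1, shark, st)
  expect_equal(m1$mld_km, d_tag + 0.3)
  expect_equal(m1$endpoint_a, "tagging-location")

  # three stations: the reported pair equals the brute-force maximum
  dets3 <- dplyr::bind_rows(dets, day_of_dets("2015-03-03", "C", "t1", 2))
  pairs <- utils::combn(1:3, 2)
  d_all <- great_circle_km(st$lat[pairs[1, ]], st$lon[pairs[1, ]],
                           st$lat[pairs[2, ]], st$lon[pairs[2, ]])
  m3 <- minimum_linear_displacement(dets3, shark, st)
  expect_equal(m3$mld_km, max(d_all) + 0.6)
  expect_setequal(c(m3$endpoint_a, m3$endpoint_b),
                  st$station_id[pairs[, which.max(d_all)]])
  expect_equal(m3$n_islands, 2L)
  expect_true(m3$long_distance == (m3$mld_km > 50))

  # duplicating detections at existing stations never changes MLD
  m_dup <- minimum_linear_displacement(dplyr::bind_rows(dets3, dets3, dets), shark, st)
  expect_equal(m_dup$mld_km, m3$mld_km)
})

test_that("utilization index implements the printed formula and ranks stations", {
  cfg <- toy_config()
  wd <- tibble::tibble(station_id = c("A", "B", "C"),
                       working_days = c(200L, 200L, 400L),
                       excluded = FALSE)
  # A: 2 sharks, 3 station-detection-days; B: 1 shark, 1 day; C: none
  dets <- dplyr::bind_rows(
    day_of_dets("2015-03-01", "A", "t1", 2),
    day_of_dets("2015-03-02", "A", "t1", 2),
    day_of_dets("2015-03-01", "A", "t2", 2),
    day_of_dets("2015-04-01", "B", "t2", 2)
  )
  ui <- utilization_index(dets, wd, cfg)
  tot_days <- 4 # array-wide detection days (t1: 2, t2: 2)
  expect_equal(ui$ui[ui$station_id == "A"], (2 / 2) * ((3 / 200) / tot_days))
  expect_equal(ui$ui[ui$station_id == "B"], (1 / 2) * ((1 / 200) / tot_days))
  expect_equal(ui$ui[ui$station_id == "C"], 0)
  expect_equal(ui$station_id[1], "A") # sorted by descending UI
  expect_equal(ui$n_sharks[ui$station_id == "C"], 0L)

  # single-station array, one shark detected every working day:
  # UI = 1 x (1 / total detection days)
  wd1 <- tibble::tibble(station_id = "A", working_days = 10L, excluded = FALSE)
  dets1 <- dplyr::bind_rows(purrr::map(1:10, ~ day_of_dets(
    as.Date("2015-03-01") + .x - 1, "A", "t1", 2)))
  ui1 <- utilization_index(dets1, wd1, cfg)
  expect_equal(ui1$ui, 1 * (1 / 10))
})

test_that("monthly activity index multiplies detection-day and shark proportions", {
  cfg <- toy_config()
  cal <- toy_deployments() # 3 stations, full 2 years
  # two sharks; both active in July, one in January
  dets <- dplyr::bind_rows(
    day_of_dets("2015-07-01", "A", "t1", 2),
    day_of_dets("2015-07-02", "A", "t1", 2),
    day_of_dets("2015-07-01", "B", "t2", 2),
    day_of_dets("2015-01-10", "A", "t2", 2)
  )
  ai <- activity_index(dets, cal, cfg)
  # July: 3 shark-detection-days over 2 Julys x 3 stations x 31 days
  expect_equal(ai$ai[ai$month == 7], (3 / (31 * 3 * 2)) * (2 / 2))
  expect_equal(ai$ai[ai$month == 1], (1 / (31 * 3 * 2)) * (1 / 2))
  expect_equal(ai$ai[ai$month == 3], 0) # month with no detections
  expect_true(all(ai$ai >= 0 & ai$ai <= 1, na.rm = TRUE))

  # saturation: every shark on every station-day of a month -> AI = 1
  cfg1 <- study_config("2015-07-01", "2015-07-31")
  cal1 <- tibble::tibble(receiver_serial = "101", station_id = "A",
                         start_date = as.Date("2015-07-01"),
                         end_date = as.Date("2015-07-31"))
  dets1 <- dplyr::bind_rows(purrr::map(1:31, ~ day_of_dets(
    as.Date("2015-07-01") + .x - 1, "A", "t1", 2)))
  ai1 <- activity_index(dets1, cal1, cfg1)
  expect_equal(ai1$ai[ai1$month == 7], 1)
  # months never covered by a working receiver are reported absent
  expect_true(all(is.na(ai1$ai[ai1$month != 7])))
})

test_that("summer-boosted presence puts the activity peak in a summer month", {
  cfg <- toy_config()
  cal <- toy_deployments()
  set.seed(91)
  days <- seq(as.Date("2015-01-01"), as.Date("2016-12-31"), by = "day")
  p <- ifelse(lubridate::month(days) %in% 4:9, 0.5, 0.1)
  dets <- purrr::map(c("t1", "t2", "t3"), function(tg) {
    present <- days[runif(length(days)) < p]
    dplyr::bind_rows(purrr::map(present, ~ day_of_dets(.x, "A", tg, 2)))
  }) |> dplyr::bind_rows()
  ai <- activity_index(dets, cal, cfg)
  expect_true(which.max(ai$ai) %in% 4:9)
})

test_that("site-fidelity decays with distance from the primary receiver", {
  # site-faithful sharks: most detections at home, fewer at farther stations
  cfg <- toy_config()
  st <- tibble::tibble(
    station_id = sprintf("S%d", 1:5), island = "I1",
    lat = 19.3 + (0:4) * 0.03, lon = -81.2
  )
  set.seed(17)
  dets <- purrr::map(1:8, function(i) {
    home <- sample(1:5, 1)
    d_home <- great_circle_km(st$lat[home], st$lon[home], st$lat, st$lon)
    w <- exp(-d_home / 2)
    n_days <- round(3 + 40 * w)
    purrr::map2(st$station_id, n_days, function(s, nd) {
      if (nd == 0) return(NULL)
      purrr::map(seq_len(nd), ~ day_of_dets(as.Date("2015-03-01") + .x + home,
                                            s, paste0("s", i), 2))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  usage <- station_usage(dets, cfg)
  prim <- usage |> dplyr::filter(rank == 1) |>
    dplyr::select(tag_id, primary = station_id)
  df <- usage |>
    dplyr::left_join(prim, by = "tag_id") |>
    dplyr::left_join(st, by = "station_id") |>
    dplyr::left_join(dplyr::select(st, primary = station_id, plat = lat, plon = lon),
                     by = "primary") |>
    dplyr::mutate(dist = great_circle_km(lat, lon, plat, plon)) |>
    dplyr::filter(dist > 0)
  rho <- spearman_rank(df$sfi, df$dist)$estimate
  expect_lt(rho, 0)
})
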
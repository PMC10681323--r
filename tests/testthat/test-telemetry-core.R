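test_that("detection files parse, tolerate isolated bad timestamps, and abort past tolerance", {
  cfg <- toy_config()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Date and Time (UTC),Receiver,Transmitter",
    "2015-07-04 10:00:00,VR2W-101,A69-1602-9001",
    "2015-07-04 10:02:00,VR2W-101,A69-1602-9001",
    "2015-07-04 11:00:00,VR2W-102,A69-1602-9002"
  ), f)
  d <- read_detections(f, cfg)
  expect_equal(nrow(d), 3)
  expect_equal(d$receiver_serial, c("101", "101", "102"))
  expect_equal(d$tag_id, c("9001", "9001", "9002"))
  expect_s3_class(d$timestamp_utc, "POSIXct")

  # empty file with header
  writeLines("Date and Time (UTC),Receiver,Transmitter", f)
  expect_equal(nrow(read_detections(f, cfg)), 0)

  # 1 bad timestamp among 100 at 5% tolerance: 99 kept, 1 rejected with line
  rows <- sprintf("2015-07-%02d 10:%02d:00,VR2W-101,A69-1602-9001",
                  rep(1:10, each = 10), rep(0:9, 10))
  rows[42] <- "not-a-time,VR2W-101,A69-1602-9001"
  writeLines(c("Date and Time (UTC),Receiver,Transmitter", rows), f)
  expect_warning(d <- read_detections(f, cfg), "unparseable")
  expect_equal(nrow(d), 99)
  expect_equal(attr(d, "rejected")$line, 43) # header is line 1

  # above tolerance the load aborts; missing column is a configuration error
  writeLines(c("Date and Time (UTC),Receiver,Transmitter",
               rep("bad,VR2W-101,A69-1602-9001", 10)), f)
  expect_error(read_detections(f, cfg), "unparseable")
  writeLines("When,Receiver,Transmitter", f)
  expect_error(read_detections(f, cfg), "missing required column")
})

test_that("station resolution follows the deployment calendar and shifts to local time", {
  cfg <- toy_config()
  st <- toy_stations()
  # serial 101 moves from A to B on 2015-06-01
  cal <- tibble::tibble(
    receiver_serial = "101", station_id = c("A", "B"),
    start_date = as.Date(c("2015-01-01", "2015-06-01")),
    end_date = as.Date(c("2015-05-31", NA))
  )
  raw <- raw_det(c("2015-05-31 12:00:00", "2015-06-02 12:00:00"), "101", "t1")
  out <- resolve_stations(raw, cal, st, cfg)
  expect_equal(out$station_id, c("A", "B"))
  # UTC-5: local time lags UTC by 5 h
  expect_equal(out$timestamp_local, raw$timestamp_utc - 5 * 3600)

  # detection before the first deployment interval is dropped and counted
  early <- raw_det("2014-12-20 12:00:00", "101", "t1")
  expect_message(out2 <- resolve_stations(rbind(early, raw), cal, st, cfg),
                 "no covering deployment")
  expect_equal(nrow(out2), 2)
  expect_equal(attr(out2, "n_dropped_unresolved"), 1L)

  # record counts are conserved: duplicates + unresolved + kept = input
  dup <- rbind(raw, raw[1, ])
  out3 <- suppressMessages(resolve_stations(rbind(early, dup), cal, st, cfg))
  expect_equal(nrow(out3) + attr(out3, "n_dropped_unresolved") +
                 attr(out3, "n_dropped_duplicate"), nrow(early) + nrow(dup))

  # overlapping intervals for a serial are a data-integrity error
  bad_cal <- tibble::tibble(
    receiver_serial = "101", station_id = c("A", "B"),
    start_date = as.Date(c("2015-01-01", "2015-05-01")),
    end_date = as.Date(c("2015-06-30", NA))
  )
  expect_error(resolve_stations(raw, bad_cal, st, cfg), "overlapping")
})

test_that("local-time shift preserves per-tag detection order", {
  cfg <- toy_config()
  set.seed(11)
  raw <- raw_det(format(lubridate::ymd_hms("2015-03-01 00:00:00", tz = "UTC") +
                          sort(runif(50, 0, 86400 * 30)), "%Y-%m-%d %H:%M:%S"),
                 "101", sample(c("t1", "t2"), 50, TRUE))
  out <- resolve_stations(raw, toy_deployments(), toy_stations(), cfg)
  per_tag <- split(out$timestamp_local, out$tag_id)
  for (v in per_tag) expect_false(is.unsorted(v))
})

test_that("single-detection days are removed per tag, idempotently", {
  # tag with 1 detection on day 1 and 5 on day 2: the single goes, 5 stay
  d <- dplyr::bind_rows(
    day_of_dets("2015-03-01", "A", "t1", 1),
    day_of_dets("2015-03-02", "A", "t1", 5)
  )
  out <- remove_single_detections(d)
  expect_equal(nrow(out), 5)
  expect_equal(unique(out$date_local), as.Date("2015-03-02"))
  expect_equal(attr(out, "n_removed"), 1L)

  # two detections of the same tag on one day at different stations survive
  # (the rule is array-wide, not per station)
  d2 <- dplyr::bind_rows(
    loc_det("2015-03-01 10:00:00", "A", "t1"),
    loc_det("2015-03-01 15:00:00", "B", "t1")
  )
  expect_equal(nrow(remove_single_detections(d2)), 2)

  # a tag with >= 2 detections every day is unchanged; empty input passes
  d3 <- dplyr::bind_rows(day_of_dets("2015-03-01", "A", "t2", 2),
                         day_of_dets("2015-03-02", "A", "t2", 3))
  expect_tbl_equal(remove_single_detections(d3), d3)
  expect_equal(nrow(remove_single_detections(d3[0, ])), 0)

  # idempotence
  once <- remove_single_detections(d)
  twice <- remove_single_detections(once)
  expect_tbl_equal(once, twice)
})

test_that("working days add over disjoint intervals and gate station inclusion", {
  cfg <- toy_config()
  # full 2015 coverage inside a 2-year window
  cal <- tibble::tibble(receiver_serial = "101", station_id = "A",
                        start_date = as.Date("2015-01-01"),
                        end_date = as.Date("2015-12-31"))
  wd <- station_working_days(cal, cfg)
  expect_equal(wd$working_days, 365L)

  # 100-day and 50-day intervals with a gap add to 150
  cal2 <- tibble::tibble(
    receiver_serial = "101", station_id = "A",
    start_date = as.Date(c("2015-01-01", "2015-08-01")),
    end_date = as.Date(c("2015-01-01", "2015-08-01")) + c(99, 49)
  )
  expect_equal(station_working_days(cal2, cfg)$working_days, 150L)

  # 120 working days fall short of the six-month rule
  cal3 <- tibble::tibble(receiver_serial = "101", station_id = "A",
                         start_date = as.Date("2015-01-01"),
                         end_date = as.Date("2015-01-01") + 119)
  wd3 <- station_working_days(cal3, cfg)
  expect_true(wd3$excluded)
  expect_false(station_working_days(cal, cfg)$excluded)

  # additivity property over random disjoint interval sets
  set.seed(3)
  for (i in 1:5) {
    starts <- sort(sample(0:600, 4)) # gaps guaranteed by spacing
    starts <- starts[c(TRUE, diff(starts) > 40)]
    lens <- sample(5:30, length(starts), TRUE)
    cal_i <- tibble::tibble(
      receiver_serial = "101", station_id = "A",
      start_date = as.Date("2015-01-01") + starts,
      end_date = as.Date("2015-01-01") + starts + lens
    )
    expect_equal(station_working_days(cal_i, cfg)$working_days, sum(lens + 1))
  }
})

test_that("the pipeline driver produces a populated, deterministic summary", {
  cfg <- sim_scenario("minimal", seed = 5)
  sim <- simulate_sharks(cfg)
  res1 <- run_pipeline(sim$detections, sim$stations, sim$deployments,
                       sim$sharks, sim$config)
  expect_s3_class(res1, "reef_analysis")
  expect_equal(nrow(res1$per_shark), 5)
  expect_true(all(c("ri", "cr", "mld_km", "sfi_primary", "n_receivers") %in%
                    names(res1$per_shark)))
  detected <- res1$per_shark$n_detections > 0
  expect_true(all(!is.na(res1$per_shark$ri[detected])))

  # re-running on the same inputs reproduces the result exactly
  res2 <- run_pipeline(sim$detections, sim$stations, sim$deployments,
                       sim$sharks, sim$config)
  expect_identical(tidy(res1), tidy(res2))
  expect_identical(res1$networks$summer$adjacency, res2$networks$summer$adjacency)

  # a never-detected tag keeps a row with zero detections and no RI/CR/SFI
  ghost <- toy_shark("ghost", tagging = format(cfg$study_start + 10))
  ghost$island <- "I1"
  sharks2 <- dplyr::bind_rows(sim$sharks, ghost)
  res3 <- run_pipeline(sim$detections, sim$stations, sim$deployments,
                       sharks2, sim$config)
  row <- dplyr::filter(tidy(res3), tag_id == "ghost")
  expect_equal(row$n_detections, 0L)
  expect_true(is.na(row$ri) && is.na(row$cr) && is.na(row$sfi_primary))

  # tidy/glance expose the per-shark table and cohort summary
  expect_equal(nrow(glance(res1)), 1)
  expect_equal(glance(res1)$n_tagged, 5)
})
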
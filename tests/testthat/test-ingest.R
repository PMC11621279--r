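write_lines_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_readings parses well-formed rows in timestamp order", {
  path <- write_lines_csv(c(
    "participant_id,timestamp,bpm",
    "P1,2024-01-01T10:02:00,80",
    "P1,2024-01-01T10:00:00,72.5",
    "P1,2024-01-01T10:00:30,95"
  ))
  rr <- read_readings(path)
  expect_identical(nrow(rr), 3L)
  expect_true(!is.unsorted(rr$timestamp))
  expect_equal(rr$bpm, c(72.5, 95, 80))
})

test_that("read_readings reports malformed rows by number and tolerates empty files", {
  bad <- write_lines_csv(c(
    "participant_id,timestamp,bpm",
    "P1,2024-01-01T10:00:00,72",
    "P1,2024-01-01T10:01:00,abc"
  ))
  expect_error(read_readings(bad), "row 2")
  bad_ts <- write_lines_csv(c(
    "participant_id,timestamp,bpm",
    "P1,not-a-time,72"
  ))
  expect_error(read_readings(bad_ts), "row 1")
  empty <- write_lines_csv("participant_id,timestamp,bpm")
  expect_identical(nrow(read_readings(empty)), 0L)
})

test_that("two readings in the same minute are both retained at ingest", {
  path <- write_lines_csv(c(
    "participant_id,timestamp,bpm",
    "P1,2024-01-01T10:00:10,72",
    "P1,2024-01-01T10:00:50,95"
  ))
  expect_identical(nrow(read_readings(path)), 2L)
})

test_that("read_labels handles all-negative files, duplicates and empties", {
  nine <- write_lines_csv(c(
    "participant_id,date,stressful",
    sprintf("P2,2024-02-%02d,0", 1:9)
  ))
  ll <- read_labels(nine)
  expect_identical(nrow(ll), 9L)
  expect_true(all(ll$stressful == 0L))

  dup <- write_lines_csv(c(
    "participant_id,date,stressful",
    "P1,2024-01-01,0",
    "P1,2024-01-01,1"
  ))
  expect_error(read_labels(dup), "duplicate")

  expect_error(read_labels(write_lines_csv(c(
    "participant_id,date,stressful", "P1,2024-01-01,2"))), "stressful")

  empty <- write_lines_csv("participant_id,date,stressful")
  expect_identical(nrow(read_labels(empty)), 0L)
})

test_that("group_by_day splits at local midnight and keeps one-sided days", {
  rr <- mk_readings(c("2024-01-01 23:59:00", "2024-01-02 00:01:00"), c(60, 61))
  ll <- tibble::tibble(participant_id = "P1", date = as.Date("2024-03-01"),
                       stressful = 1L)
  days <- group_by_day(rr, ll)
  expect_identical(nrow(days), 3L)
  day1 <- days[days$date == as.Date("2024-01-01"), ]
  expect_identical(day1$n_readings, 1L)
  expect_true(is.na(day1$stressful))            # readings, no label
  labeled <- days[days$date == as.Date("2024-03-01"), ]
  expect_identical(labeled$n_readings, 0L)       # label, no readings
  expect_identical(labeled$stressful, 1L)
})

test_that("hour_coverage counts distinct clock hours with a reading", {
  full <- mk_readings(sprintf("2024-01-01 %02d:30:00", 0:23), rep(70, 24))
  morning <- mk_readings(c("2024-01-01 09:05:00", "2024-01-01 10:15:00",
                           "2024-01-01 11:59:00"), c(70, 71, 72))
  labels <- tibble::tibble(participant_id = "P9", date = as.Date("2024-01-05"),
                           stressful = 0L)
  days <- group_by_day(dplyr::bind_rows(
    full, dplyr::mutate(morning, participant_id = "P2")), labels)
  cov <- hour_coverage(days)
  expect_identical(cov[days$participant_id == "P1"], 24L)
  expect_identical(cov[days$participant_id == "P2"], 3L)
  expect_identical(cov[days$participant_id == "P9"], 0L)
})

test_that("filter_valid_days applies the strict >21-hour rule with a label", {
  co <- small_cohort()
  days <- group_by_day(co$readings, co$labels)
  vd <- filter_valid_days(days)
  cov <- hour_coverage(vd)
  expect_true(all(cov > 21))
  expect_true(all(!is.na(vd$stressful)))

  # boundary: exactly 21 covered hours is dropped
  rr21 <- mk_readings(sprintf("2024-01-01 %02d:30:00", 0:20), rep(70, 21))
  ll <- tibble::tibble(participant_id = "P1", date = as.Date("2024-01-01"),
                       stressful = 0L)
  d21 <- group_by_day(rr21, ll)
  expect_identical(nrow(filter_valid_days(d21)), 0L)
  expect_identical(nrow(filter_valid_days(d21, min_hours_exclusive = 20)), 1L)
})

test_that("filtering is idempotent, monotone in the threshold, and matches a brute-force recount", {
  cfg <- sim_config(n_participants = 1, n_days = 40, p_hour_missing = 0.3, seed = 17)
  co <- simulate_cohort(cfg)
  days <- group_by_day(co$readings, co$labels)
  vd <- filter_valid_days(days)
  expect_identical(filter_valid_days(vd), vd)

  counts <- vapply(18:24, function(th) nrow(filter_valid_days(days, th)), integer(1))
  expect_true(all(diff(counts) <= 0))

  # brute force straight from the raw tables
  rd <- dplyr::mutate(co$readings, date = as.Date(timestamp, tz = "UTC"),
                      hour = as.integer(format(timestamp, "%H", tz = "UTC")))
  cov <- rd |>
    dplyr::group_by(participant_id, date) |>
    dplyr::summarise(cov = dplyr::n_distinct(hour), .groups = "drop")
  brute <- dplyr::inner_join(cov, co$labels, by = c("participant_id", "date"))
  brute <- brute[brute$cov > 21, ]
  expect_identical(nrow(vd), nrow(brute))
  expect_setequal(format(vd$date), format(brute$date))
})

test_that("cohort_summary aggregates per participant and matches recounts", {
  rr <- dplyr::bind_rows(
    mk_readings(sprintf("2024-01-01 10:%02d:00", 0:9), rep(70, 10)),
    mk_readings(sprintf("2024-01-02 10:%02d:00", 0:19), rep(70, 20))
  )
  days <- group_by_day(rr, tibble::tibble(participant_id = character(),
                                          date = as.Date(character()),
                                          stressful = integer()))
  s <- cohort_summary(days)
  expect_equal(s$mean_readings_per_day, 15)
  expect_identical(s$days_with_both, 0L)

  co <- small_cohort()
  days2 <- group_by_day(co$readings, co$labels)
  s2 <- cohort_summary(days2)
  for (pid in s2$participant_id) {
    sub <- days2[days2$participant_id == pid, ]
    expect_identical(s2$days_with_readings[s2$participant_id == pid],
                     sum(sub$n_readings > 0))
    expect_identical(s2$days_with_both[s2$participant_id == pid],
                     sum(sub$n_readings > 0 & !is.na(sub$stressful)))
    expect_equal(s2$mean_readings_per_day[s2$participant_id == pid],
                 mean(sub$n_readings[sub$n_readings > 0]))
  }
})
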
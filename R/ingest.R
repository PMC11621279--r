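#' Read wearable heart-rate readings from CSV
#'
#' Expects the dialect `participant_id,timestamp,bpm` with ISO-8601 local
#' timestamps (`T` or space separated, minute or finer resolution) and
#' positive numeric bpm. Malformed rows are reported by row number.
#'
#' @param paths One or more CSV paths; results are concatenated.
#' @param tz Time zone the timestamps are interpreted in (the cohort is
#'   assumed to live in a single zone).
#' @return Tibble `participant_id,timestamp,bpm` sorted by participant then
#'   timestamp. An empty file (header only) yields an empty tibble.
#' @export
read_readings <- function(paths, tz = "UTC") {
  out <- purrr::map(paths, function(path) {
    if (!file.exists(path)) stop("readings file not found: ", path, call. = FALSE)
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    need <- c("participant_id", "timestamp", "bpm")
    if (!all(need %in% names(raw))) {
      stop("readings file ", path, " must have columns ",
           paste(need, collapse = ","), call. = FALSE)
    }
    if (nrow(raw) == 0) {
      return(tibble::tibble(participant_id = character(),
                            timestamp = as.POSIXct(character(), tz = tz),
                            bpm = double()))
    }
    bpm <- suppressWarnings(as.numeric(raw$bpm))
    bad <- which(is.na(bpm) | bpm <= 0)
    if (length(bad) > 0) {
      stop("unparseable or non-positive bpm in ", path, " at row ", bad[1],
           " (value `", raw$bpm[bad[1]], "`)", call. = FALSE)
    }
    ts <- parse_iso_ts(raw$timestamp, tz)
    bad <- which(is.na(ts))
    if (length(bad) > 0) {
      stop("malformed timestamp in ", path, " at row ", bad[1],
           " (value `", raw$timestamp[bad[1]], "`)", call. = FALSE)
    }
    tibble::tibble(participant_id = raw$participant_id, timestamp = ts, bpm = bpm)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$participant_id, .data$timestamp)
}

parse_iso_ts <- function(x, tz) {
  x <- sub("T", " ", x, fixed = TRUE)
  ts <- as.POSIXct(x, tz = tz, format = "%Y-%m-%d %H:%M:%S")
  miss <- is.na(ts)
  if (any(miss)) {  # minute-resolution timestamps
    ts[miss] <- as.POSIXct(x[miss], tz = tz, format = "%Y-%m-%d %H:%M")
  }
  ts
}

#' Read daily stress labels from CSV
#'
#' Dialect `participant_id,date,stressful` with `stressful` in \{0, 1\}
#' (1 = the participant reported a stressful day). Duplicate
#' (participant, date) rows are rejected.
#'
#' @param path CSV path.
#' @return Tibble `participant_id,date,stressful` with `date` as `Date` and
#'   `stressful` integer.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("participant_id", "date", "stressful")
  if (!all(need %in% names(raw))) {
    stop("labels file must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(participant_id = character(), date = as.Date(character()),
                          stressful = integer()))
  }
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(date))
  if (length(bad) > 0) {
    stop("unparseable date at row ", bad[1], " (value `", raw$date[bad[1]], "`)",
         call. = FALSE)
  }
  if (!all(raw$stressful %in% c("0", "1"))) {
    bad <- which(!raw$stressful %in% c("0", "1"))[1]
    stop("`stressful` must be 0 or 1; row ", bad, " has `", raw$stressful[bad], "`",
         call. = FALSE)
  }
  out <- tibble::tibble(participant_id = raw$participant_id, date = date,
                        stressful = as.integer(raw$stressful))
  dup <- duplicated(out[c("participant_id", "date")])
  if (any(dup)) {
    d <- out[which(dup)[1], ]
    stop("duplicate label for participant ", d$participant_id, " on ",
         format(d$date), call. = FALSE)
  }
  out
}

#' Assemble participant-days from readings and labels
#'
#' Produces one row per participant-day that has at least one reading or a
#' label -- the unit of analysis. Days with readings but no label
#' (label never entered) carry `stressful = NA`; days with a label but no
#' readings (device not worn) carry an empty readings tibble. Both patterns
#' are reported by [cohort_summary()] and removed by [filter_valid_days()].
#'
#' @param readings Tibble from [read_readings()].
#' @param labels Tibble from [read_labels()].
#' @param tz Time zone defining the local calendar-day boundary.
#' @return Tibble `participant_id,date,n_readings,stressful,readings` where
#'   `readings` is a list-column of per-day `timestamp,bpm` tibbles sorted
#'   in time.
#' @export
group_by_day <- function(readings, labels, tz = "UTC") {
  rd <- dplyr::mutate(readings, date = as.Date(.data$timestamp, tz = tz))
  rd <- dplyr::arrange(rd, .data$participant_id, .data$timestamp)
  by_day <- rd |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    tidyr::nest(readings = c("timestamp", "bpm")) |>
    dplyr::ungroup()
  out <- dplyr::full_join(by_day, labels, by = c("participant_id", "date"))
  empty <- tibble::tibble(timestamp = as.POSIXct(character(), tz = tz), bpm = double())
  out$readings <- purrr::map(out$readings, function(r) if (is.null(r)) empty else r)
  out <- dplyr::mutate(out,
                       n_readings = purrr::map_int(.data$readings, nrow),
                       stressful = as.integer(.data$stressful))
  out <- dplyr::arrange(out, .data$participant_id, .data$date)
  out[, c("participant_id", "date", "n_readings", "stressful", "readings")]
}

#' Hour coverage of participant-days
#'
#' An hour counts as covered when at least one reading falls inside that
#' local clock hour; the result is the number of distinct covered hours in
#' \{0, ..., 23\}.
#'
#' @param days Day-record tibble from [group_by_day()] (or any tibble with
#'   a `readings` list-column of `timestamp` tibbles).
#' @param tz Time zone used to extract the clock hour.
#' @return Integer vector, one 0-24 count per row of `days`.
#' @export
hour_coverage <- function(days, tz = "UTC") {
  purrr::map_int(days$readings, function(r) {
    if (is.null(r) || nrow(r) == 0) return(0L)
    length(unique(as.integer(format(r$timestamp, "%H", tz = tz))))
  })
}

#' Filter participant-days to the valid-day set
#'
#' A valid day has (a) a stress label and (b) heart-rate readings in more
#' than `min_hours_exclusive` of the 24 clock hours (strict inequality: a
#' coverage of exactly 21 hours is dropped at the default threshold).
#'
#' @param days Day-record tibble from [group_by_day()].
#' @param min_hours_exclusive Coverage threshold (hours, exclusive).
#'   Default 21, i.e. at least 22 covered hours.
#' @param tz Time zone for the clock-hour computation.
#' @return The retained rows of `days`, original order preserved.
#' @export
filter_valid_days <- function(days, min_hours_exclusive = 21, tz = "UTC") {
  cov <- hour_coverage(days, tz = tz)
  days[!is.na(days$stressful) & cov > min_hours_exclusive, , drop = FALSE]
}

#' Per-participant cohort summary
#'
#' Mirrors the exploratory counts one reports before filtering: days with
#' readings, days with labels, days with both, mean readings per day (over
#' days with readings), mean hour coverage, and quartiles of the per-day
#' reading count.
#'
#' @param days Day-record tibble from [group_by_day()].
#' @param tz Time zone for coverage.
#' @return One summary row per participant.
#' @export
cohort_summary <- function(days, tz = "UTC") {
  days$._cov <- hour_coverage(days, tz = tz)
  days |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      days_with_readings = sum(.data$n_readings > 0),
      days_with_labels = sum(!is.na(.data$stressful)),
      days_with_both = sum(.data$n_readings > 0 & !is.na(.data$stressful)),
      mean_readings_per_day = mean(.data$n_readings[.data$n_readings > 0]),
      mean_hour_coverage = mean(.data$._cov[.data$n_readings > 0]),
      readings_q1 = stats::quantile(.data$n_readings[.data$n_readings > 0], 0.25, names = FALSE),
      readings_median = stats::median(.data$n_readings[.data$n_readings > 0]),
      readings_q3 = stats::quantile(.data$n_readings[.data$n_readings > 0], 0.75, names = FALSE),
      .groups = "drop"
    )
}
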
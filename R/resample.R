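#' Construct a minute series
#'
#' A minute series holds one bpm slot per minute of the (fragment of a)
#' day, plus a provenance mask saying whether each slot was observed,
#' forward-filled from the previous observation, or backward-filled from
#' the first observation of the day. A full day has 1440 slots; shorter
#' series are allowed so that toy fragments can be pushed through the same
#' fill/downsample rules.
#'
#' @param values Numeric vector, `NA` for empty slots.
#' @param mask Optional character vector the same length, entries in
#'   `"observed"`, `"forward_filled"`, `"backward_filled"` or `NA`.
#' @return A `minute_series` object.
#' @export
minute_series <- function(values, mask = NULL) {
  values <- as.numeric(values)
  if (is.null(mask)) mask <- ifelse(is.na(values), NA_character_, "observed")
  stopifnot(length(mask) == length(values))
  ok <- is.na(mask) | mask %in% c("observed", "forward_filled", "backward_filled")
  if (!all(ok)) stop("invalid provenance mask entries", call. = FALSE)
  structure(list(values = values, mask = mask), class = "minute_series")
}

#' @exportS3Method base::print
print.minute_series <- function(x, ...) {
  n_obs <- sum(x$mask == "observed", na.rm = TRUE)
  cat("<minute_series> ", length(x$values), " slots, ", n_obs, " observed, ",
      sum(is.na(x$values)), " empty\n", sep = "")
  invisible(x)
}

#' Per-minute maximum resampling of one day's raw readings
#'
#' Assigns each raw reading to its minute-of-day slot and keeps the maximum
#' bpm per slot -- the maximum (rather than the mean) is used so that brief
#' heart-rate surges are highlighted instead of averaged away. Slots whose
#' minute received no reading stay empty until [fill_missing()].
#'
#' @param readings Tibble with `timestamp` (POSIXct) and `bpm` for a single
#'   participant-day, or one row of the [group_by_day()] table.
#' @param tz Time zone used to compute minute-of-day.
#' @return A partial [minute_series()] of length 1440.
#' @export
minute_resample <- function(readings, tz = "UTC") {
  if (is.data.frame(readings) && "readings" %in% names(readings) &&
      !("timestamp" %in% names(readings))) {
    stopifnot(nrow(readings) == 1)
    readings <- readings$readings[[1]]
  }
  if (is.null(readings) || nrow(readings) == 0) {
    stop("cannot resample a day with no readings", call. = FALSE)
  }
  minute <- as.integer(format(readings$timestamp, "%H", tz = tz)) * 60L +
    as.integer(format(readings$timestamp, "%M", tz = tz))
  values <- rep(NA_real_, 1440)
  mx <- tapply(readings$bpm, minute, max)
  values[as.integer(names(mx)) + 1L] <- as.numeric(mx)
  minute_series(values)
}

#' Fill the empty slots of a minute series
#'
#' Interior and trailing gaps take the immediately preceding observed value
#' (carry-forward: heart rate is assumed stable while the device is
#' silent); slots before the first observation take the first observed
#' value (carry-backward, typically covering sleep). The mask records which
#' rule produced each slot.
#'
#' @param series A partial [minute_series()].
#' @return A complete `minute_series` (no empty slots).
#' @export
fill_missing <- function(series) {
  stopifnot(inherits(series, "minute_series"))
  v <- series$values
  obs <- which(!is.na(v))
  if (length(obs) == 0) stop("minute series has no observed slots", call. = FALSE)
  idx <- findInterval(seq_along(v), obs)   # index of latest observation <= slot
  filled <- v[obs[pmax(idx, 1L)]]
  mask <- series$mask
  mask[idx == 0L] <- "backward_filled"
  mask[idx > 0L & is.na(v)] <- "forward_filled"
  minute_series(filled, mask)
}

#' Downsample a complete minute series to a coarser day vector
#'
#' Aggregates non-overlapping `granularity_minutes`-wide windows aligned at
#' minute 0 with a window reducer (maximum by default, consistent with the
#' per-minute rule). A full 1440-slot day at the default 3-minute
#' granularity yields the 480-point day vector used by every feature
#' modality.
#'
#' @param series A complete [minute_series()] (no `NA` slots).
#' @param granularity_minutes Window width; must divide the series length
#'   unless `partial = TRUE`.
#' @param reducer Window aggregation function, default `max`.
#' @param partial If `TRUE`, a shorter trailing window is aggregated too
#'   (useful for day fragments); if `FALSE` (default), a non-divisor
#'   granularity is a configuration error.
#' @return Numeric vector of length `ceiling(length(series) /
#'   granularity_minutes)`.
#' @export
downsample <- function(series, granularity_minutes = 3, reducer = max,
                       partial = FALSE) {
  stopifnot(inherits(series, "minute_series"))
  v <- series$values
  if (anyNA(v)) stop("downsample requires a filled series; call fill_missing() first",
                     call. = FALSE)
  g <- as.integer(granularity_minutes)
  if (g < 1 || (!partial && length(v) %% g != 0)) {
    stop("granularity_minutes (", granularity_minutes,
         ") must divide the series length (", length(v), ")", call. = FALSE)
  }
  win <- (seq_along(v) - 1L) %/% g
  as.numeric(tapply(v, win, reducer))
}

#' Direct coarse resampling without the 1-minute stage
#'
#' Takes the per-window maximum of the *raw* observations only, dropping
#' windows containing no reading. Provided as the comparison path showing
#' why two-stage processing (1-minute fill, then downsample) is preferred:
#' the direct path loses carried-forward values, so the two disagree
#' whenever a window is empty or only partially observed.
#'
#' @param x A partial [minute_series()] (e.g. from [minute_resample()]).
#' @param granularity_minutes Window width in minutes.
#' @return Numeric vector of per-window maxima, named by 0-based window
#'   index; empty windows are omitted.
#' @export
direct_resample <- function(x, granularity_minutes = 3) {
  stopifnot(inherits(x, "minute_series"))
  g <- as.integer(granularity_minutes)
  if (g < 1) stop("granularity_minutes must be >= 1", call. = FALSE)
  v <- x$values
  win <- (seq_along(v) - 1L) %/% g
  mx <- tapply(v, win, function(w) if (all(is.na(w))) NA_real_ else max(w, na.rm = TRUE))
  out <- as.numeric(mx)
  names(out) <- names(mx)
  out[!is.na(out)]
}

#' Regularize valid days into the day-vector matrix
#'
#' Runs the full resampling pipeline (per-minute maximum, fill, window
#' maximum downsample) over every valid day and assembles the modelling
#' table: one row per day with `participant_id`, `date`, `stressful` and
#' `hr_0 ... hr_{N-1}` columns, `N = 1440 / granularity_minutes` (480 at
#' the 3-minute default).
#'
#' @param valid_days Output of [filter_valid_days()].
#' @param granularity_minutes Downsampling granularity, must divide 1440.
#' @param tz Time zone for minute-of-day computation.
#' @param reducer Window reducer passed to [downsample()].
#' @return Tibble of day vectors; attribute `"granularity"` records the
#'   window width.
#' @export
regularize_days <- function(valid_days, granularity_minutes = 3, tz = "UTC",
                            reducer = max) {
  if (1440 %% granularity_minutes != 0) {
    stop("granularity_minutes must divide 1440", call. = FALSE)
  }
  n <- 1440 / granularity_minutes
  rows <- purrr::map(seq_len(nrow(valid_days)), function(i) {
    ms <- minute_resample(valid_days$readings[[i]], tz = tz)
    vec <- downsample(fill_missing(ms), granularity_minutes, reducer = reducer)
    stats::setNames(as.list(vec), paste0("hr_", seq_len(n) - 1L))
  })
  meta <- valid_days[, c("participant_id", "date", "stressful")]
  out <- dplyr::bind_cols(meta, dplyr::bind_rows(rows))
  attr(out, "granularity") <- granularity_minutes
  out
}

#' Extract the numeric day-vector matrix from a regularized table
#'
#' @param day_tbl Output of [regularize_days()].
#' @return Numeric matrix (days x N) with `participant_id_date` row names.
#' @export
day_matrix <- function(day_tbl) {
  hr_cols <- grep("^hr_", names(day_tbl), value = TRUE)
  X <- as.matrix(day_tbl[, hr_cols])
  rownames(X) <- paste(day_tbl$participant_id, format(day_tbl$date), sep = "_")
  X
}
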
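#' Simulation configuration for synthetic wearable heart-rate cohorts
#'
#' Bundles and validates every knob of the synthetic-stream generator. The
#' generator emulates the structure of wrist-wearable heart-rate data: a
#' circadian baseline with sleep bradycardia, transient activity bursts,
#' adaptive sampling density (the device reads more often while the heart
#' rate is elevated), hour-level dropout, occasionally missing day labels,
#' and a day-level stress effect expressed as a baseline shift, a slow
#' (2-4 h period) oscillation, and a higher burst rate.
#'
#' @param n_participants Number of simulated participants.
#' @param n_days Days simulated per participant.
#' @param stress_prevalence Probability that a day is stressful, in (0, 1).
#' @param sleep_window Pair of clock hours `c(start, end)` for sleep;
#'   wraps midnight when `start > end`.
#' @param sleep_mean_bpm,wake_mean_bpm Mean latent heart rate (bpm) while
#'   asleep / awake.
#' @param bpm_sd Between-day jitter (bpm) of the wake baseline.
#' @param burst_rate_per_day Poisson mean number of activity bursts per day.
#' @param burst_amp_range Burst peak amplitude interval (bpm).
#' @param burst_len_range Burst nominal length interval (minutes); bursts
#'   decay exponentially with time constant length/3.
#' @param stress_burst_multiplier Multiplier (>= 1) on the burst rate for
#'   stressful days.
#' @param stress_baseline_shift Additive bpm shift of the latent baseline on
#'   stressful days.
#' @param stress_lf_amp Amplitude (bpm) of a slow sinusoid (period drawn
#'   uniformly between 2 and 4 hours) added on stressful days.
#' @param rest_interval_range Inter-reading gap interval at rest, minutes.
#' @param burst_interval_range Inter-reading gap interval while the latent
#'   rate is elevated, seconds.
#' @param p_hour_missing Probability that each clock hour of a day is
#'   dropped wholesale (device off-wrist), in \[0, 1\].
#' @param p_label_missing Probability that a day's label is never entered.
#' @param noise_sd Gaussian observation noise sd (bpm); observations are
#'   clipped to \[30, 220\].
#' @param seed Integer seed; identical `sim_config()` + seed reproduce a
#'   cohort byte-for-byte.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_day()]
#' @export
sim_config <- function(n_participants = 3,
                       n_days = 70,
                       stress_prevalence = 0.3,
                       sleep_window = c(23, 7),
                       sleep_mean_bpm = 55,
                       wake_mean_bpm = 75,
                       bpm_sd = 3,
                       burst_rate_per_day = 4,
                       burst_amp_range = c(20, 60),
                       burst_len_range = c(5, 40),
                       stress_burst_multiplier = 1.8,
                       stress_baseline_shift = 3,
                       stress_lf_amp = 6,
                       rest_interval_range = c(3, 8),
                       burst_interval_range = c(10, 60),
                       p_hour_missing = 0.05,
                       p_label_missing = 0.1,
                       noise_sd = 2,
                       seed = 42L) {
  cfg <- list(
    n_participants = n_participants, n_days = n_days,
    stress_prevalence = stress_prevalence, sleep_window = sleep_window,
    sleep_mean_bpm = sleep_mean_bpm, wake_mean_bpm = wake_mean_bpm,
    bpm_sd = bpm_sd, burst_rate_per_day = burst_rate_per_day,
    burst_amp_range = burst_amp_range, burst_len_range = burst_len_range,
    stress_burst_multiplier = stress_burst_multiplier,
    stress_baseline_shift = stress_baseline_shift,
    stress_lf_amp = stress_lf_amp,
    rest_interval_range = rest_interval_range,
    burst_interval_range = burst_interval_range,
    p_hour_missing = p_hour_missing, p_label_missing = p_label_missing,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid sim_config field `", field, "`: ", what, call. = FALSE)
  }
  pos_scalar <- function(f) chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
                                  is.finite(cfg[[f]]) && cfg[[f]] > 0, f, "must be a positive number")
  count1 <- function(f) chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
                              cfg[[f]] >= 1 && cfg[[f]] == floor(cfg[[f]]), f, "must be a positive integer")
  prob1 <- function(f) chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
                             cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must lie in [0, 1]")
  ivl <- function(f) chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 2 &&
                           all(cfg[[f]] > 0) && cfg[[f]][1] <= cfg[[f]][2], f,
                         "must be a positive increasing interval")
  count1("n_participants"); count1("n_days")
  chk(cfg$stress_prevalence > 0 && cfg$stress_prevalence < 1,
      "stress_prevalence", "must lie strictly in (0, 1)")
  chk(is.numeric(cfg$sleep_window) && length(cfg$sleep_window) == 2 &&
        all(cfg$sleep_window >= 0 & cfg$sleep_window <= 24),
      "sleep_window", "must be two clock hours in [0, 24]")
  pos_scalar("sleep_mean_bpm"); pos_scalar("wake_mean_bpm"); pos_scalar("bpm_sd")
  chk(is.numeric(cfg$burst_rate_per_day) && length(cfg$burst_rate_per_day) == 1 &&
        cfg$burst_rate_per_day >= 0, "burst_rate_per_day", "must be >= 0")
  ivl("burst_amp_range"); ivl("burst_len_range")
  chk(is.numeric(cfg$stress_burst_multiplier) && cfg$stress_burst_multiplier >= 1,
      "stress_burst_multiplier", "must be >= 1")
  chk(is.numeric(cfg$stress_baseline_shift) && cfg$stress_baseline_shift >= 0,
      "stress_baseline_shift", "must be >= 0")
  chk(is.numeric(cfg$stress_lf_amp) && cfg$stress_lf_amp >= 0,
      "stress_lf_amp", "must be >= 0")
  ivl("rest_interval_range"); ivl("burst_interval_range")
  prob1("p_hour_missing"); prob1("p_label_missing")
  chk(is.numeric(cfg$noise_sd) && cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed", "must be a single integer")
  invisible(cfg)
}

# Latent heart rate as a function of seconds-since-midnight. Circadian
# baseline is piecewise (sleep/wake) smoothed with a 31-minute moving
# average; LF stress oscillation and exponentially decaying bursts are
# analytic, so the latent process can be evaluated at any 1-second instant.
make_latent_day <- function(cfg, stressful) {
  minute_hours <- (0:1439) / 60
  sw <- cfg$sleep_window
  asleep <- if (sw[1] <= sw[2]) {
    minute_hours >= sw[1] & minute_hours < sw[2]
  } else {
    minute_hours >= sw[1] | minute_hours < sw[2]
  }
  wake_mu <- cfg$wake_mean_bpm + stats::rnorm(1, 0, cfg$bpm_sd)
  base_min <- ifelse(asleep, cfg$sleep_mean_bpm, wake_mu)
  # circular moving average, 31 min, smooths sleep/wake transitions
  k <- rep(1 / 31, 31)
  base_min <- as.numeric(stats::filter(base_min, k, circular = TRUE))

  # always draw LF parameters so stress/non-stress runs stay stream-aligned
  lf_period <- stats::runif(1, 2 * 3600, 4 * 3600)
  lf_phase <- stats::runif(1, 0, 2 * pi)
  lf_amp <- if (stressful) cfg$stress_lf_amp else 0
  shift <- if (stressful) cfg$stress_baseline_shift else 0

  rate <- cfg$burst_rate_per_day *
    if (stressful) cfg$stress_burst_multiplier else 1
  n_burst <- stats::rpois(1, rate)
  b_start <- sort(stats::runif(n_burst, 0, 86400))
  b_len <- stats::runif(n_burst, cfg$burst_len_range[1], cfg$burst_len_range[2])
  b_amp <- stats::runif(n_burst, cfg$burst_amp_range[1], cfg$burst_amp_range[2])
  b_tau <- b_len * 60 / 3  # seconds; decay constant = length / 3

  latent_at <- function(t_sec) {
    m <- pmin(1439L, as.integer(t_sec %/% 60))
    v <- base_min[m + 1L] + shift +
      lf_amp * sin(2 * pi * t_sec / lf_period + lf_phase)
    if (n_burst > 0) {
      for (b in seq_len(n_burst)) {
        dt <- t_sec - b_start[b]
        v <- v + ifelse(dt >= 0, b_amp[b] * exp(-dt / b_tau[b]), 0)
      }
    }
    v
  }
  list(latent_at = latent_at, n_burst = n_burst, lf_period = lf_period,
       lf_phase = lf_phase, wake_mu = wake_mu)
}

#' Simulate one participant-day of wearable heart-rate readings
#'
#' Draws from the current R random-number stream (seed it with `set.seed()`
#' or call via [simulate_cohort()], which seeds from the config). Sampling
#' density is adaptive: while the latent rate exceeds the wake baseline by
#' more than 15 bpm, inter-reading gaps are drawn from
#' `burst_interval_range` (seconds), otherwise from `rest_interval_range`
#' (minutes) -- mirroring devices that read more often during fluctuation.
#'
#' @param cfg A [sim_config()].
#' @param date A `Date` for the simulated calendar day.
#' @param stressful Logical; applies the configured stress effects to the
#'   latent signal.
#' @param participant_id Identifier stamped on the readings.
#' @param tz Time zone of the emitted timestamps.
#' @param return_latent If `TRUE`, attach the latent minute-level signal
#'   (1440 values) as attribute `"latent_minute"`.
#' @return A tibble with columns `participant_id`, `timestamp` (POSIXct,
#'   strictly increasing, within the day) and `bpm` (clipped to
#'   \[30, 220\]), plus attribute `"day_truth"` (a one-row tibble of latent
#'   parameters).
#' @export
simulate_day <- function(cfg, date, stressful, participant_id = "P1",
                         tz = "UTC", return_latent = FALSE) {
  validate_sim_config(cfg)
  stopifnot(inherits(date, "Date"), is.logical(stressful) || stressful %in% c(0, 1))
  stressful <- as.logical(stressful)
  lat <- make_latent_day(cfg, stressful)
  threshold <- cfg$wake_mean_bpm + 15

  cap <- 200000L
  times <- numeric(cap)
  n <- 0L
  t <- stats::runif(1, 0, cfg$rest_interval_range[1] * 60)
  while (t < 86400 && n < cap) {
    n <- n + 1L
    times[n] <- t
    gap <- if (lat$latent_at(t) > threshold) {
      stats::runif(1, cfg$burst_interval_range[1], cfg$burst_interval_range[2])
    } else {
      stats::runif(1, cfg$rest_interval_range[1] * 60, cfg$rest_interval_range[2] * 60)
    }
    t <- t + gap
  }
  times <- times[seq_len(n)]
  bpm <- pmin(220, pmax(30, lat$latent_at(times) + stats::rnorm(n, 0, cfg$noise_sd)))

  # hour-level dropout: each clock hour independently lost wholesale
  drop_hour <- stats::runif(24) < cfg$p_hour_missing
  keep <- !drop_hour[as.integer(times %/% 3600) + 1L]
  times <- times[keep]
  bpm <- bpm[keep]

  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = tz)
  out <- tibble::tibble(
    participant_id = participant_id,
    timestamp = midnight + times,
    bpm = round(bpm, 1)
  )
  attr(out, "day_truth") <- tibble::tibble(
    participant_id = participant_id, date = date, stressful = as.integer(stressful),
    n_bursts = lat$n_burst, lf_period_s = lat$lf_period,
    lf_phase = lat$lf_phase, wake_mu_bpm = lat$wake_mu,
    hours_dropped = sum(drop_hour)
  )
  if (return_latent) {
    attr(out, "latent_minute") <- lat$latent_at((0:1439) * 60 + 30)
  }
  out
}

#' Simulate a full cohort of readings, labels and ground truth
#'
#' Seeds the RNG from `cfg$seed`, so identical configurations reproduce the
#' cohort exactly. Labels are dropped independently with probability
#' `p_label_missing` (emulating days the participant forgot to enter a
#' label); the truth table always retains the real label and the latent
#' day parameters for recovery tests.
#'
#' @param cfg A [sim_config()].
#' @param start_date First simulated calendar day.
#' @param tz Time zone for timestamps.
#' @return A list of class `hr_cohort` with tibbles `readings`
#'   (`participant_id,timestamp,bpm`), `labels`
#'   (`participant_id,date,stressful`) and `truth` (per-day latent
#'   parameters).
#' @export
simulate_cohort <- function(cfg, start_date = as.Date("2024-01-01"), tz = "UTC") {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  readings <- list()
  truth <- list()
  keep_label <- list()
  i <- 0L
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%d", p)
    for (d in seq_len(cfg$n_days)) {
      i <- i + 1L
      date <- start_date + (d - 1L)
      stressful <- stats::runif(1) < cfg$stress_prevalence
      day <- simulate_day(cfg, date, stressful, participant_id = pid, tz = tz)
      readings[[i]] <- day
      truth[[i]] <- attr(day, "day_truth")
      keep_label[[i]] <- stats::runif(1) >= cfg$p_label_missing
    }
  }
  truth <- dplyr::bind_rows(truth)
  labels <- truth[unlist(keep_label), c("participant_id", "date", "stressful")]
  structure(
    list(
      readings = dplyr::bind_rows(readings),
      labels = labels,
      truth = truth
    ),
    class = "hr_cohort"
  )
}

#' Write a simulated cohort to the CSV dialects the ingest module reads
#'
#' Emits one `readings_<participant>.csv` per participant
#' (`participant_id,timestamp,bpm`, ISO-8601 timestamps), a single
#' `labels.csv` (`participant_id,date,stressful`) and `truth.csv` (labels
#' plus latent parameters). Round-trips losslessly through
#' [read_readings()] / [read_labels()].
#'
#' @param cohort An `hr_cohort` from [simulate_cohort()], or any list with
#'   `readings` and `labels` tibbles.
#' @param dir Output directory (created if absent).
#' @return Named list of written file paths (`readings`, `labels`, `truth`).
#' @export
write_fixture <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create fixture directory: ", dir, call. = FALSE)
  pids <- unique(cohort$readings$participant_id)
  if (length(pids) == 0 && nrow(cohort$labels) > 0) {
    pids <- character(0)
  }
  rpaths <- character(0)
  fmt_ts <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S")
  if (length(pids) == 0) {
    # empty cohort: still write one valid readings file with a header
    path <- file.path(dir, "readings_empty.csv")
    readr::write_csv(tibble::tibble(participant_id = character(),
                                    timestamp = character(), bpm = double()), path)
    rpaths <- path
  } else {
    for (pid in pids) {
      sub <- dplyr::filter(cohort$readings, .data$participant_id == pid)
      sub <- dplyr::mutate(sub, timestamp = fmt_ts(.data$timestamp))
      path <- file.path(dir, paste0("readings_", pid, ".csv"))
      readr::write_csv(sub, path)
      rpaths <- c(rpaths, path)
    }
  }
  lpath <- file.path(dir, "labels.csv")
  readr::write_csv(cohort$labels, lpath)
  tpath <- NULL
  if (!is.null(cohort$truth)) {
    tpath <- file.path(dir, "truth.csv")
    readr::write_csv(cohort$truth, tpath)
  }
  list(readings = rpaths, labels = lpath, truth = tpath)
}
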
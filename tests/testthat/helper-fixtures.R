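# Shared fixtures, built once per session and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# The printed 10-minute toy fragment: readings at minutes 0, 2, 7, 8.
toy_series <- function() {
  minute_series(c(58, NA, 67, NA, NA, NA, NA, 61, 62, NA))
}

# Tiny cohort for ingest/resample plumbing tests.
small_cohort <- function() {
  memo("small_cohort", function() {
    cfg <- sim_config(n_participants = 2, n_days = 10, seed = 31)
    simulate_cohort(cfg)
  })
}

small_valid_days <- function() {
  memo("small_valid_days", function() {
    co <- small_cohort()
    truth_labels <- co$truth[, c("participant_id", "date", "stressful")]
    filter_valid_days(group_by_day(co$readings, truth_labels))
  })
}

small_day_tbl <- function() {
  memo("small_day_tbl", function() regularize_days(small_valid_days()))
}

# Strong-effect study cohort: 200 days, LF amplitude 8 bpm, burst rate
# multiplier 1.8 -- the conditions of the pipeline power check.
strong_cfg <- function(seed = 42) {
  sim_config(n_participants = 1, n_days = 200, stress_lf_amp = 8,
             stress_burst_multiplier = 1.8, seed = seed)
}

null_cfg <- function(seed = 42) {
  sim_config(n_participants = 1, n_days = 200, stress_lf_amp = 0,
             stress_burst_multiplier = 1, stress_baseline_shift = 0, seed = seed)
}

cohort_day_tbl <- function(cfg) {
  truth_labels <- NULL
  co <- simulate_cohort(cfg)
  truth_labels <- co$truth[, c("participant_id", "date", "stressful")]
  regularize_days(filter_valid_days(group_by_day(co$readings, truth_labels)))
}

strong_day_tbl <- function() memo("strong_day_tbl", function() cohort_day_tbl(strong_cfg()))
null_day_tbl <- function() memo("null_day_tbl", function() cohort_day_tbl(null_cfg()))

# Feature matrix with a known mean shift on the positive class, for
# classifier plumbing tests.
shifted_features <- function(n = 80, p = 12, shift = 1.5, prev = 0.35, seed = 2) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n)
  y <- stats::rbinom(n, 1, prev)
  X[y == 1, 1:3] <- X[y == 1, 1:3] + shift
  structure(list(X = X, labels = y, modality = "org"), class = "feature_set")
}

# Readings tibble helper for hand-built days.
mk_readings <- function(times, bpm, pid = "P1", tz = "UTC") {
  tibble::tibble(
    participant_id = pid,
    timestamp = as.POSIXct(times, tz = tz),
    bpm = bpm
  )
}

# Nadeau-Bengio corrected standard error for repeated k-fold accuracies:
# fold results share training data, so the naive sd/sqrt(n) underestimates.
corrected_se <- function(fold_values, folds = 10) {
  n <- length(fold_values)
  stats::sd(fold_values) * sqrt(1 / n + 1 / (folds - 1))
}
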
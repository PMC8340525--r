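# All generator randomness flows from one seed, split into fixed
# sub-streams (AR path, measurement noise, outliers, diastolic noise, ...)
# so adding a feature never shifts the draws of existing ones.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream)
}

#' Parameters of the synthetic blood pressure stream
#'
#' The generator emulates a home-monitoring stream with the phenomena the
#' display has to tame: a circadian rhythm, slowly wandering day-to-day
#' level (AR(1)), independent cuff noise, a white-coat offset added to
#' office readings, occasional outliers, medication-response drops with an
#' onset delay, and runs of missing data. It is a test-bed process, not a
#' physiological model. Diastolic values are generated as a 0.62-slope
#' coupling to the systolic deviation plus independent noise, clipped to
#' keep systolic > diastolic.
#'
#' @param baseline_sbp,baseline_dbp resting means in mmHg (defaults 135/84,
#'   an uncontrolled hypertensive).
#' @param circadian_amplitude mmHg amplitude of the within-day sinusoid.
#' @param ar1_rho lag-1 correlation of the wandering level, in \[0, 1).
#' @param noise_sd mmHg; both the stationary sd of the AR(1) level and the
#'   sd of the per-reading noise.
#' @param office_offset mmHg added to office readings (white-coat effect).
#' @param outlier_rate per-reading probability of an outlier.
#' @param outlier_shift mmHg magnitude of an outlier (random sign).
#' @param cadence_minutes home-reading cadence; `NA` for no home stream.
#' @param office_interval_days days between office visits; 0 for none.
#' @param med_effects list of `list(start =, drop =, onset_days =)`: each
#'   course lowers systolic by `drop` mmHg through a sigmoid beginning at
#'   `start + onset_days`.
#' @param seed integer seed; the same seed reproduces the same series.
#' @return A `bp_sim_params` object.
#' @export
sim_params <- function(baseline_sbp = 135, baseline_dbp = 84,
                       circadian_amplitude = 8, ar1_rho = 0.6,
                       noise_sd = 7, office_offset = 10,
                       outlier_rate = 0.02, outlier_shift = 30,
                       cadence_minutes = 720, office_interval_days = 30,
                       med_effects = list(), seed = 1L) {
  stopifnot(noise_sd >= 0, outlier_rate >= 0, outlier_rate <= 1,
            ar1_rho >= 0, ar1_rho < 1, circadian_amplitude >= 0)
  structure(list(baseline_sbp = baseline_sbp, baseline_dbp = baseline_dbp,
                 circadian_amplitude = circadian_amplitude,
                 ar1_rho = ar1_rho, noise_sd = noise_sd,
                 office_offset = office_offset,
                 outlier_rate = outlier_rate, outlier_shift = outlier_shift,
                 cadence_minutes = cadence_minutes,
                 office_interval_days = office_interval_days,
                 med_effects = med_effects, seed = as.integer(seed)),
            class = "bp_sim_params")
}

med_effect_at <- function(days_since_window, med_effects, window_start) {
  eff <- rep(0, length(days_since_window))
  for (m in med_effects) {
    d0 <- as.numeric(as_bp_time(m$start)) / DAY -
      as.numeric(window_start) / DAY
    d <- days_since_window - d0 - m$onset_days
    eff <- eff - m$drop * stats::plogis(d / 1)
  }
  eff
}

#' Simulate a blood pressure monitoring stream
#'
#' Generates home readings at the configured cadence plus office visits at
#' the configured interval over `window`. Each reading is
#' `baseline + circadian sinusoid + AR(1) level + noise
#'  (+ office offset if an office reading) (+ outlier shift)
#'  (+ medication-response drop)`,
#' deterministic given `params$seed`. Values are clipped to the physiologic
#' bounds (with a warning) so the output always satisfies the measurement
#' invariants.
#'
#' @param params a [sim_params()].
#' @param window length-2 window (start, end).
#' @return A `bp_measurements` frame sorted by timestamp.
#' @examples
#' s <- simulate_bp_series(sim_params(seed = 7), c("2021-07-01", "2021-08-01"))
#' head(s)
#' @export
simulate_bp_series <- function(params, window) {
  stopifnot(inherits(params, "bp_sim_params"))
  w <- as_bp_time(window)
  stopifnot(length(w) == 2L, w[1] < w[2])
  ts <- numeric()
  src <- character()
  if (!is.na(params$cadence_minutes)) {
    home_ts <- seq(as.numeric(w[1]), as.numeric(w[2]) - 1,
                   by = params$cadence_minutes * 60)
    ts <- c(ts, home_ts)
    src <- c(src, rep("home", length(home_ts)))
  }
  if (params$office_interval_days > 0) {
    k <- seq_len(floor((as.numeric(w[2]) - as.numeric(w[1])) /
                         (params$office_interval_days * DAY)))
    office_ts <- as.numeric(w[1]) +
      (k - 0.5) * params$office_interval_days * DAY
    # pin visits to 10:00 clinic time on their day
    office_ts <- (office_ts %/% DAY) * DAY + 10 * 3600
    office_ts <- office_ts[office_ts >= as.numeric(w[1]) &
                             office_ts < as.numeric(w[2])]
    ts <- c(ts, office_ts)
    src <- c(src, rep("office", length(office_ts)))
  }
  if (length(ts) == 0L) return(empty_measurements())
  o <- order(ts)
  ts <- ts[o]
  src <- src[o]
  n <- length(ts)

  days <- (ts - as.numeric(w[1])) / DAY
  hod <- (ts / 3600) %% 24
  circadian <- params$circadian_amplitude * sin(2 * pi * (hod - 9) / 24)

  ar <- with_local_seed(sub_seed(params$seed, 1L), {
    if (params$noise_sd == 0 || n == 0L) {
      rep(0, n)
    } else {
      innov <- stats::rnorm(n, 0, params$noise_sd * sqrt(1 - params$ar1_rho^2))
      z <- numeric(n)
      z[1] <- stats::rnorm(1, 0, params$noise_sd)
      for (i in seq_len(n)[-1]) z[i] <- params$ar1_rho * z[i - 1] + innov[i]
      z
    }
  })
  eps <- with_local_seed(sub_seed(params$seed, 2L),
                         stats::rnorm(n, 0, params$noise_sd))
  outl <- with_local_seed(sub_seed(params$seed, 3L), {
    hit <- stats::runif(n) < params$outlier_rate
    sign <- sample(c(-1, 1), n, replace = TRUE)
    ifelse(hit, sign * params$outlier_shift, 0)
  })
  eps_d <- with_local_seed(sub_seed(params$seed, 4L),
                           stats::rnorm(n, 0, 0.6 * params$noise_sd))

  med <- med_effect_at(days, params$med_effects, w[1])
  sbp <- params$baseline_sbp + circadian + ar + eps + outl + med +
    ifelse(src == "office", params$office_offset, 0)
  dbp <- params$baseline_dbp + 0.62 * (sbp - params$baseline_sbp) + eps_d

  lo <- BP_BOUNDS[[1]]; hi <- BP_BOUNDS[[2]]
  clipped <- sbp < lo + 1 | sbp > hi | dbp < lo | dbp > hi | dbp >= sbp
  if (any(clipped)) {
    warning(sum(clipped), " generated value(s) clipped to physiologic bounds",
            call. = FALSE)
  }
  sbp <- pmin(pmax(sbp, lo + 1), hi)
  dbp <- pmin(pmax(dbp, lo), hi)
  dbp <- pmin(dbp, sbp - 1)

  new_bp_measurements(data.frame(
    timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
    systolic = sbp, diastolic = dbp, source = src,
    confirmed = rep(FALSE, n)))
}

#' Simulate paired home/office readings at shared instants
#'
#' Emulates cuff-validation visits: at each of `n` instants one home and
#' one office reading share the same latent blood pressure, so the mean
#' office-minus-home difference isolates the configured white-coat offset
#' (sampling error `noise_sd * sqrt(2/n)`).
#'
#' @param params a [sim_params()].
#' @param n number of pairs.
#' @return data frame `pair`, `source`, `systolic`, `diastolic`.
#' @export
simulate_paired_readings <- function(params, n) {
  stopifnot(inherits(params, "bp_sim_params"), n >= 1)
  latent <- with_local_seed(sub_seed(params$seed, 11L),
                            params$baseline_sbp + stats::rnorm(n, 0, params$noise_sd))
  e_home <- with_local_seed(sub_seed(params$seed, 12L),
                            stats::rnorm(n, 0, params$noise_sd))
  e_off <- with_local_seed(sub_seed(params$seed, 13L),
                           stats::rnorm(n, 0, params$noise_sd))
  sbp_home <- latent + e_home
  sbp_off <- latent + params$office_offset + e_off
  dbp <- function(s) params$baseline_dbp + 0.62 * (s - params$baseline_sbp)
  data.frame(
    pair = rep(seq_len(n), 2L),
    source = rep(c("home", "office"), each = n),
    systolic = c(sbp_home, sbp_off),
    diastolic = c(dbp(sbp_home), dbp(sbp_off)),
    stringsAsFactors = FALSE)
}

#' Remove measurements inside missing-data runs
#'
#' Deletes every measurement whose timestamp falls inside any run
#' `[start, end)`. Overlapping runs are merged first (with a warning).
#' An empty run list returns the series unchanged.
#'
#' @param series a `bp_measurements` frame.
#' @param runs data frame with `start` and `end` columns (datetimes or
#'   ISO strings), or an empty list.
#' @return the filtered `bp_measurements` frame.
#' @export
inject_missingness <- function(series, runs) {
  stopifnot(inherits(series, "bp_measurements"))
  if (is.null(runs) || length(runs) == 0L ||
      (is.data.frame(runs) && nrow(runs) == 0L)) {
    return(series)
  }
  stopifnot(is.data.frame(runs), all(c("start", "end") %in% names(runs)))
  s <- as.numeric(as_bp_time(runs$start))
  e <- as.numeric(as_bp_time(runs$end))
  stopifnot(all(e > s))
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  merged_s <- c(); merged_e <- c(); merged_any <- FALSE
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
      merged_any <- TRUE
    } else {
      merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
  if (merged_any) warning("overlapping missing runs merged", call. = FALSE)
  t <- as.numeric(series$timestamp)
  drop <- rep(FALSE, length(t))
  for (i in seq_along(merged_s)) {
    drop <- drop | (t >= merged_s[i] & t < merged_e[i])
  }
  new_bp_measurements(series[!drop, , drop = FALSE])
}

#' Canned demonstration scenarios
#'
#' Three seeded scenarios mirroring the eras of home BP data density:
#' `"dearth"` (office-only readings every 13 weeks over two years),
#' `"nascence"` (weekly home readings plus monthly office visits over six
#' months, with a lisinopril dose increase mid-way), and `"abundance"`
#' (10-minute wearable cadence over two weeks). Each returns measurements,
#' a medication list, annotations and a matching display window.
#'
#' @param preset `"dearth"`, `"nascence"` or `"abundance"`.
#' @param seed integer seed.
#' @return list with `measurements`, `medications`, `annotations`,
#'   `window`, `params`.
#' @export
simulate_scenario <- function(preset = c("nascence", "dearth", "abundance"),
                              seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "dearth") {
    window <- as_bp_time(c("2020-01-01", "2022-01-01"))
    meds <- medication_courses(
      c("Lisinopril", "Lisinopril"), c("10 mg daily", "20 mg daily"),
      c("2020-06-01", "2021-02-01"), c("2021-02-01", NA))
    params <- sim_params(
      cadence_minutes = NA, office_interval_days = 91, seed = seed,
      med_effects = list(list(start = "2020-06-01", drop = 8, onset_days = 10),
                         list(start = "2021-02-01", drop = 6, onset_days = 10)))
    ann <- bp_annotations(c("2020-06-01", "2021-02-01"),
                          c("Started lisinopril 10 mg",
                            "Dose increased to 20 mg"),
                          "provider")
  } else if (preset == "nascence") {
    window <- as_bp_time(c("2021-01-01", "2021-07-01"))
    meds <- medication_courses(
      c("Lisinopril", "Lisinopril"), c("10 mg daily", "20 mg daily"),
      c("2021-02-01", "2021-04-15"), c("2021-04-15", NA))
    params <- sim_params(
      cadence_minutes = 7 * 24 * 60, office_interval_days = 30, seed = seed,
      med_effects = list(list(start = "2021-02-01", drop = 8, onset_days = 7),
                         list(start = "2021-04-15", drop = 6, onset_days = 7)))
    ann <- bp_annotations(c("2021-03-10", "2021-05-01"),
                          c("Started low-sodium diet",
                            "Walking 30 min after dinner"),
                          "patient")
  } else {
    window <- as_bp_time(c("2021-06-01", "2021-06-15"))
    meds <- medication_courses("Amlodipine", "5 mg daily",
                               "2021-01-01", NA)
    params <- sim_params(cadence_minutes = 10, office_interval_days = 7,
                         seed = seed)
    ann <- bp_annotations("2021-06-08", "New wearable cuff paired", "patient")
  }
  list(measurements = simulate_bp_series(params, window),
       medications = meds, annotations = ann,
       window = window, params = params)
}
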
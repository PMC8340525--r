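test_that("the density schedule maps every listed period to its bin width and cap", {
  rows <- list(
    list(1, 1800, 48L), list(7, 10800, 56L), list(14, 21600, 56L),
    list(31, 43200, 62L), list(62, 86400, 62L), list(123, 2 * 86400, 62L),
    list(184, 3 * 86400, 62L), list(366, 7 * 86400, 54L),
    list(731, 14 * 86400, 54L), list(1827, 31 * 86400, 60L),
    list(3653, 62 * 86400, 60L), list(5479, 123 * 86400, 60L),
    list(10958, 184 * 86400, 60L))
  for (r in rows) {
    sch <- select_bin_schedule(r[[1]])
    expect_equal(sch$bin_seconds, r[[2]], info = paste(r[[1]], "days"))
    expect_equal(sch$max_points, r[[3]], info = paste(r[[1]], "days"))
  }
})

test_that("unlisted window lengths snap up to the next listed period", {
  sch <- select_bin_schedule(10)           # 10 days -> 2-week row
  expect_equal(sch$window_label, "2 weeks")
  expect_equal(sch$bin_seconds, 6 * 3600)
  expect_equal(sch$max_points, 56L)
  expect_equal(select_bin_schedule(63)$window_label, "4 months")
  expect_equal(select_bin_schedule(40 * 366)$window_label, ">30 years")
  expect_error(select_bin_schedule(0), "NonPositiveWindow")
  expect_error(select_bin_schedule(-3), "NonPositiveWindow")
})

test_that("bin grids are window-anchored, half-open, and capped", {
  b <- make_bins("2021-07-01", "2021-09-01")   # July + August, daily bins
  expect_equal(nrow(b), 62L)
  expect_equal(b$start[1], as.POSIXct("2021-07-01", tz = "UTC"))
  expect_equal(b$end[62], as.POSIXct("2021-09-01", tz = "UTC"))
  expect_equal(as.numeric(b$end - b$start, units = "days"), rep(1, 62))

  b <- make_bins("2021-07-01", "2021-07-02")   # one day, 30-min bins
  expect_equal(nrow(b), 48L)

  expect_error(make_bins("2021-07-01", "2021-07-01"), "NonPositiveWindow")
})

test_that("every schedule row keeps dense input at or under its cap (and 62 overall)", {
  tab <- bpdisplay:::bin_schedule_table()
  start <- as.POSIXct("2020-01-01", tz = "UTC")
  for (i in seq_len(nrow(tab) - 1L)) {
    period <- tab$period_days[i]
    sch <- select_bin_schedule(period)
    b <- make_bins(start, start + period * 86400, sch)
    expect_lte(nrow(b), sch$max_points)
    expect_lte(nrow(b), 62L)
    # a measurement in every bin still cannot exceed the cap
    ms <- bp_measurements(b$start + 60, 120, 80, "home")
    pts <- aggregate_measurements(ms, b)
    expect_equal(nrow(pts), nrow(b))
  }
  # random window lengths (snap-up) never overflow either
  set.seed(99)
  for (days in sort(c(runif(25, 0.5, 10958), 366, 731))) {
    sch <- select_bin_schedule(days)
    b <- make_bins(start, start + days * 86400, sch)
    expect_lte(nrow(b), sch$max_points)
  }
})

test_that("aggregation averages bin members and assigns the majority symbol", {
  bins <- make_bins("2021-07-01", "2021-09-01")
  ms <- bp_measurements(
    c("2021-07-01 08:00", "2021-07-01 20:00", "2021-07-02 08:00"),
    c(120, 130, 118), c(80, 90, 76), c("home", "home", "home"))
  pts <- aggregate_measurements(ms, bins)
  expect_equal(pts$mean_systolic, c(125, 118))
  expect_equal(pts$mean_diastolic, c(85, 76))
  expect_equal(pts$n_measurements, c(2L, 1L))
  expect_equal(pts$is_aggregate, c(TRUE, FALSE))
  expect_equal(pts$source_symbol, c("circle_home", "circle_home"))

  # 2 home + 1 office -> circle; 1-1 tie -> square; office majority -> square
  mixed <- bp_measurements(
    c("2021-07-05 08:00", "2021-07-05 12:00", "2021-07-05 18:00",
      "2021-07-06 08:00", "2021-07-06 12:00",
      "2021-07-07 08:00"),
    120, 80,
    c("home", "home", "office", "home", "office", "inpatient"))
  pts <- aggregate_measurements(mixed, bins)
  expect_equal(pts$source_symbol,
               c("circle_home", "square_office", "square_office"))
})

test_that("aggregation conserves the grand mean and partitions measurements", {
  for (seed in 1:3) {
    s <- simulate_bp_series(sim_params(seed = seed, cadence_minutes = 97),
                            c("2021-07-01", "2021-09-01"))
    bins <- make_bins("2021-07-01", "2021-09-01")
    pts <- aggregate_measurements(s, bins)
    expect_equal(sum(pts$n_measurements), nrow(s))  # each row in exactly one bin
    expect_equal(sum(pts$n_measurements * pts$mean_systolic) /
                   sum(pts$n_measurements),
                 mean(s$systolic), tolerance = 1e-9)
    expect_equal(sum(pts$n_measurements * pts$mean_diastolic) /
                   sum(pts$n_measurements),
                 mean(s$diastolic), tolerance = 1e-9)
    # bin means stay inside their members' range
    idx <- findInterval(as.numeric(s$timestamp), as.numeric(bins$start))
    for (k in seq_len(nrow(pts))) {
      member <- s$systolic[idx == pts$bin_index[k]]
      expect_gte(pts$mean_systolic[k], min(member) - 1e-12)
      expect_lte(pts$mean_systolic[k], max(member) + 1e-12)
    }
  }
})

test_that("missing runs under the threshold stay solid, above it turn dashed", {
  n_bins <- 62L
  # one missing run of 5 bins (8.1% of the window): everything solid
  pts <- aggregate_measurements(
    measurements_in_bins(setdiff(1:62, 21:25)), make_bins("2021-07-01", "2021-09-01"))
  seg <- classify_segments(pts, n_bins, 0.10)
  expect_true(all(seg$style == "solid"))

  # one missing run of 10 bins (16.1%): exactly one dashed bridge
  pts <- aggregate_measurements(
    measurements_in_bins(setdiff(1:62, 21:30)), make_bins("2021-07-01", "2021-09-01"))
  seg <- classify_segments(pts, n_bins, 0.10)
  expect_equal(sum(seg$style == "dashed"), 1L)
  expect_equal(seg$gap_bins[seg$style == "dashed"], 10L)

  # no missing bins: a single solid polyline
  pts <- aggregate_measurements(measurements_in_bins(1:62),
                                make_bins("2021-07-01", "2021-09-01"))
  seg <- classify_segments(pts, n_bins, 0.10)
  expect_equal(nrow(seg), 61L)
  expect_true(all(seg$style == "solid"))
})

test_that("the threshold comparison is strict: exactly 10% renders solid", {
  # with 100 bins the boundary is attainable exactly
  win <- c("2020-01-01", "2020-04-10")  # 100 days -> snaps to 4-month row
  bins <- make_bins(win[1], win[2], structure(
    list(window_label = "test", bin_seconds = 86400, max_points = 100L),
    class = "bp_bin_schedule"))
  expect_equal(nrow(bins), 100L)
  mk <- function(gap_len) {
    occupied <- setdiff(1:100, seq(40, length.out = gap_len))
    ts <- as.POSIXct("2020-01-01 09:00", tz = "UTC") + (occupied - 1) * 86400
    pts <- aggregate_measurements(bp_measurements(ts, 120, 80, "home"), bins)
    classify_segments(pts, 100L, 0.10)
  }
  expect_true(all(mk(10)$style == "solid"))     # 10/100 = threshold -> solid
  expect_equal(sum(mk(11)$style == "dashed"), 1L)
})

test_that("segment styles depend only on the empty-bin mask", {
  bins <- make_bins("2021-07-01", "2021-09-01")
  occupied <- setdiff(1:62, c(5:12, 40:42))
  a <- aggregate_measurements(measurements_in_bins(occupied, sbp = 120), bins)
  b <- aggregate_measurements(measurements_in_bins(occupied, sbp = 180,
                                                   dbp = 110), bins)
  expect_identical(classify_segments(a, 62L, 0.10),
                   classify_segments(b, 62L, 0.10))
})

test_that("filling an empty bin never turns a solid segment dashed", {
  set.seed(7)
  bins <- make_bins("2021-07-01", "2021-09-01")
  for (rep in 1:20) {
    occupied <- sort(sample(1:62, sample(5:30, 1)))
    empty <- setdiff(1:62, occupied)
    if (length(empty) == 0L) next
    before <- classify_segments(
      aggregate_measurements(measurements_in_bins(occupied), bins), 62L, 0.10)
    add <- sample(empty, 1)
    after <- classify_segments(
      aggregate_measurements(measurements_in_bins(sort(c(occupied, add))),
                             bins), 62L, 0.10)
    # every dashed segment after the insertion lies within a previously
    # dashed gap: insertion only splits runs, never lengthens them
    for (k in which(after$style == "dashed")) {
      covering <- before$from_bin <= after$from_bin[k] &
        before$to_bin >= after$to_bin[k]
      expect_true(any(before$style[covering] == "dashed"))
    }
  }
})

test_that("zero non-empty bins raises the no-points condition", {
  empty <- aggregate_measurements(
    bp_measurements(character(), numeric(), numeric()),
    make_bins("2021-07-01", "2021-09-01"))
  expect_error(classify_segments(empty, 62L, 0.10), class = "bp_no_points")
})

test_that("calendar enumeration reproduces the schedule's worked maxima", {
  expect_equal(max_consecutive_month_days(2), 62L)    # July + August
  expect_equal(max_consecutive_month_days(4), 123L)
  expect_equal(max_consecutive_month_days(6), 184L)
  weeks <- vapply(1990:2035, calendar_week_count, integer(1))
  expect_equal(max(weeks), 54L)
  expect_true(all(weeks >= 53L))
})
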
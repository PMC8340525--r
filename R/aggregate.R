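# Density schedule: each supported display period maps to a bin width and a
# point cap, so that any window shows at most 62 points in graph and table.
# Month-denominated bin widths are fixed at their calendar maxima in days
# (31, 62, 123, 184, 366) so the cap holds for any window snapped to the row.
DAY <- 86400

bin_schedule_table <- function() {
  data.frame(
    window_label = c("1 day", "1 week", "2 weeks", "1 month", "2 months",
                     "4 months", "6 months", "1 year", "2 years", "5 years",
                     "10 years", "15 years", "30 years", ">30 years"),
    period_days = c(1, 7, 14, 31, 62, 123, 184, 366, 731,
                    1827, 3653, 5479, 10958, 21915),
    bin_seconds = c(1800, 10800, 21600, 43200, DAY, 2 * DAY, 3 * DAY,
                    7 * DAY, 14 * DAY, 31 * DAY, 62 * DAY, 123 * DAY,
                    184 * DAY, 366 * DAY),
    max_points = c(48L, 56L, 56L, 62L, 62L, 62L, 62L, 54L, 54L,
                   60L, 60L, 60L, 60L, 60L),
    stringsAsFactors = FALSE)
}

#' Select the bin width and point cap for a display window
#'
#' Maps a requested window length onto the display's density schedule:
#' each listed period carries a bin width and a maximum number of display
#' points (never more than 62). An unlisted length snaps up to the smallest
#' listed period that covers it, so the cap is never exceeded.
#'
#' | period | bin width | max points |
#' |--------|-----------|-----------:|
#' | 1 day | 30 min | 48 |
#' | 1 week | 3 h | 56 |
#' | 2 weeks | 6 h | 56 |
#' | 1 month | 12 h | 62 |
#' | 2 months | 1 day | 62 |
#' | 4 months | 2 days | 62 |
#' | 6 months | 3 days | 62 |
#' | 1 year | 1 week | 54 |
#' | 2 years | 2 weeks | 54 |
#' | 5 years | 1 month | 60 |
#' | 10 years | 2 months | 60 |
#' | 15 years | 4 months | 60 |
#' | 30 years | 6 months | 60 |
#' | beyond | 1 year | 60 |
#'
#' @param window window length: a `difftime`, or a number of days.
#' @return A `bp_bin_schedule` list: `window_label`, `bin_seconds`,
#'   `max_points`.
#' @examples
#' select_bin_schedule(62)          # 2 months -> 1-day bins, cap 62
#' select_bin_schedule(as.difftime(1, units = "days"))
#' @export
select_bin_schedule <- function(window) {
  days <- if (inherits(window, "difftime")) {
    as.numeric(window, units = "days")
  } else {
    as.numeric(window)
  }
  if (!is.finite(days) || days <= 0) {
    stop("NonPositiveWindow: window must be a positive duration", call. = FALSE)
  }
  tab <- bin_schedule_table()
  i <- which(tab$period_days >= days - 1e-9)[1]
  if (is.na(i)) i <- nrow(tab)  # beyond 30 years: 1-year bins, cap 60
  structure(list(window_label = tab$window_label[i],
                 bin_seconds = tab$bin_seconds[i],
                 max_points = tab$max_points[i]),
            class = "bp_bin_schedule")
}

#' Build the bin grid for a window
#'
#' Half-open intervals `[start, start + w), [start + w, start + 2w), ...`
#' anchored at the window start (not calendar-aligned), covering the whole
#' window. The count never exceeds the schedule's point cap.
#'
#' @param start,end window bounds (datetimes, `Date`s or ISO strings),
#'   `start < end`.
#' @param schedule a `bp_bin_schedule` from [select_bin_schedule()]; by
#'   default selected from the window length itself.
#' @return data frame with `bin_index`, `start`, `end` (POSIXct).
#' @examples
#' nrow(make_bins("2021-07-01", "2021-09-01"))  # July + August: 62 daily bins
#' @export
make_bins <- function(start, end, schedule = NULL) {
  start <- as_bp_time(start)
  end <- as_bp_time(end)
  total <- as.numeric(end, "secs") - as.numeric(start, "secs")
  if (!is.finite(total) || total <= 0) {
    stop("NonPositiveWindow: window start must precede end", call. = FALSE)
  }
  if (is.null(schedule)) {
    schedule <- select_bin_schedule(total / DAY)
  }
  stopifnot(inherits(schedule, "bp_bin_schedule"))
  w <- schedule$bin_seconds
  n <- as.integer(ceiling(total / w - 1e-9))
  if (n > schedule$max_points) {
    stop("CapExceeded: ", n, " bins exceed the ", schedule$max_points,
         "-point cap for the '", schedule$window_label, "' schedule row",
         call. = FALSE)
  }
  starts <- start + (seq_len(n) - 1L) * w
  data.frame(bin_index = seq_len(n), start = starts, end = starts + w)
}

#' Aggregate measurements into display bins
#'
#' Each non-empty bin yields one display point: the arithmetic mean of its
#' members' systolic and diastolic pressures (kept unrounded internally;
#' the data table renders integers), the member count, and a source symbol —
#' a circle if the majority of members are home readings, a square otherwise
#' (ties go to the office square, whose values are staff-validated). Empty
#' bins yield no point. Each measurement falls in exactly one half-open bin.
#'
#' @param ms a `bp_measurements` frame (measurements outside the bin grid
#'   are ignored).
#' @param bins bin grid from [make_bins()].
#' @return A `bp_aggregated` data frame: `bin_index`, `start`, `end`,
#'   `mean_systolic`, `mean_diastolic`, `n_measurements`, `source_symbol`,
#'   `is_aggregate`.
#' @export
aggregate_measurements <- function(ms, bins) {
  stopifnot(is.data.frame(ms), is.data.frame(bins))
  t0 <- as.numeric(bins$start[1])
  t1 <- as.numeric(bins$end[nrow(bins)])
  ts <- as.numeric(ms$timestamp)
  keep <- !is.na(ts) & ts >= t0 & ts < t1
  ms <- ms[keep, , drop = FALSE]
  out_proto <- data.frame(
    bin_index = integer(), start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    mean_systolic = numeric(), mean_diastolic = numeric(),
    n_measurements = integer(), source_symbol = character(),
    is_aggregate = logical(), stringsAsFactors = FALSE)
  if (nrow(ms) == 0L) {
    class(out_proto) <- c("bp_aggregated", "data.frame")
    return(out_proto)
  }
  idx <- findInterval(as.numeric(ms$timestamp), as.numeric(bins$start))
  groups <- sort(unique(idx))
  home_like <- ms$source %in% c("home", "ambulatory")
  n_i <- as.integer(tapply(idx, idx, length)[as.character(groups)])
  out <- data.frame(
    bin_index = groups,
    start = bins$start[groups],
    end = bins$end[groups],
    mean_systolic = as.numeric(tapply(ms$systolic, idx, mean)[as.character(groups)]),
    mean_diastolic = as.numeric(tapply(ms$diastolic, idx, mean)[as.character(groups)]),
    n_measurements = n_i,
    stringsAsFactors = FALSE)
  n_home <- as.integer(tapply(home_like, idx, sum)[as.character(groups)])
  out$source_symbol <- ifelse(n_home * 2L > out$n_measurements,
                              "circle_home", "square_office")
  out$is_aggregate <- out$n_measurements > 1L
  rownames(out) <- NULL
  class(out) <- c("bp_aggregated", "data.frame")
  out
}

#' Classify line segments over missing-data runs
#'
#' The polyline between adjacent non-empty bins is solid. A maximal run of
#' `L` empty bins in a window of `n_bins` bins is bridged by a single
#' segment whose style is dashed when `L / n_bins > threshold` (strictly;
#' exactly at the threshold renders solid) and solid otherwise, so the
#' amount of missing data can be read from the line style alone — no points
#' are plotted for the gap and the data table keeps its gap rows.
#'
#' @param points `bp_aggregated` points indexed against the bin grid.
#' @param n_bins total number of bins in the window.
#' @param threshold fraction of window bins in (0, 1); default 0.10.
#' @return data frame with `from_bin`, `to_bin`, `gap_bins`, `style`
#'   (`"solid"`/`"dashed"`), one row per adjacent pair of plotted points.
#' @export
classify_segments <- function(points, n_bins, threshold = 0.10) {
  stopifnot(threshold > 0, threshold < 1, n_bins >= 1)
  if (is.null(points) || nrow(points) == 0L) {
    stop(structure(class = c("bp_no_points", "error", "condition"),
                   list(message = "NoPoints: no non-empty bins in the window",
                        call = NULL)))
  }
  occ <- sort(unique(points$bin_index))
  if (length(occ) < 2L) {
    return(data.frame(from_bin = integer(), to_bin = integer(),
                      gap_bins = integer(), style = character(),
                      stringsAsFactors = FALSE))
  }
  from <- occ[-length(occ)]
  to <- occ[-1]
  gap <- to - from - 1L
  data.frame(from_bin = from, to_bin = to, gap_bins = gap,
             style = ifelse(gap / n_bins > threshold, "dashed", "solid"),
             stringsAsFactors = FALSE)
}

#' Calendar maxima behind the density schedule's point caps
#'
#' `max_consecutive_month_days()` enumerates every run of `n_months`
#' consecutive calendar months across `years` and returns the largest total
#' day count — e.g. 62 for any 2-month span (July + August), 123 for 4
#' months, 184 for 6 months. `calendar_week_count()` counts the distinct
#' Monday-anchored calendar weeks a year touches (at most 54). These are the
#' quantities that justify the schedule's per-row caps.
#'
#' @param n_months number of consecutive calendar months.
#' @param years years over which to enumerate starting months (spanning
#'   leap and non-leap years).
#' @return `max_consecutive_month_days()`: the maximum day count (integer).
#' @examples
#' max_consecutive_month_days(2)   # 62
#' max(vapply(2000:2030, calendar_week_count, integer(1)))  # 54
#' @export
max_consecutive_month_days <- function(n_months, years = 2019:2024) {
  firsts <- as.Date(vapply(years, function(y) {
    sprintf("%d-%02d-01", y, 1:12)
  }, character(12)))
  firsts <- sort(firsts)
  # need n_months beyond each start; drop starts whose span is not covered
  usable <- seq_len(length(firsts) - n_months)
  spans <- vapply(usable, function(i) {
    as.integer(firsts[i + n_months] - firsts[i])
  }, integer(1))
  max(spans)
}

#' @rdname max_consecutive_month_days
#' @param year a calendar year.
#' @return `calendar_week_count()`: the number of distinct calendar weeks
#'   (Monday-start) intersecting the year.
#' @export
calendar_week_count <- function(year) {
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  # 1970-01-01 was a Thursday; +3 shifts the epoch to a Monday week start
  length(unique((as.integer(days) + 3L) %/% 7L))
}
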
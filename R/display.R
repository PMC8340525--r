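#' Classify a reading against the goal range
#'
#' Per channel, with inclusive bounds: `below` if the value is under the
#' low bound, `in_range` if `low <= value <= high`, `above` otherwise. On
#' the display this is exactly the like-with-like band test: a point sits
#' inside its matching-hue band iff its channel is `in_range`.
#'
#' @param sbp,dbp pressures in mmHg (vectorised).
#' @param goal a [goal_range()].
#' @return data frame with `systolic_status` and `diastolic_status`
#'   (`"below"`/`"in_range"`/`"above"`).
#' @examples
#' classify_goal(150, 75, goal_range())  # above, in_range
#' @export
classify_goal <- function(sbp, dbp, goal = goal_range()) {
  stopifnot(inherits(goal, "bp_goal_range"))
  band <- function(v, lo, hi) {
    ifelse(v < lo, "below", ifelse(v > hi, "above", "in_range"))
  }
  data.frame(
    systolic_status = band(sbp, goal$sbp_low, goal$sbp_high),
    diastolic_status = band(dbp, goal$dbp_low, goal$dbp_high),
    stringsAsFactors = FALSE)
}

# Half-up integer rounding for displayed values (R's round() is half-even).
round_half_up <- function(x) floor(x + 0.5)

EM_DASH <- "—"

#' Build the data table panel
#'
#' One row per bin, in window order. An empty bin becomes a gap row with
#' em-dash placeholders (gaps in the table mirror gaps in the graph). Values
#' are rounded to integers (half-up). A cell is bold when its value is out
#' of the goal range (dual encoding with the bands) or when the point
#' aggregates more than one measurement — the graph gives no visual hint of
#' aggregation, the bold table value does.
#'
#' @param points `bp_aggregated` frame.
#' @param bins bin grid from [make_bins()].
#' @param goal a [goal_range()].
#' @return data frame with `bin_index`, `label`, `systolic`, `diastolic`
#'   (display texts), `bold_systolic`, `bold_diastolic`, `gap`.
#' @export
build_data_table <- function(points, bins, goal = goal_range()) {
  n <- nrow(bins)
  sub_day <- as.numeric(bins$end[1]) - as.numeric(bins$start[1]) < DAY
  label <- format(bins$start, if (sub_day) "%H:%M" else "%Y-%m-%d")
  tab <- data.frame(
    bin_index = bins$bin_index, label = label,
    systolic = rep(EM_DASH, n), diastolic = rep(EM_DASH, n),
    bold_systolic = rep(FALSE, n), bold_diastolic = rep(FALSE, n),
    gap = rep(TRUE, n), stringsAsFactors = FALSE)
  if (!is.null(points) && nrow(points) > 0L) {
    i <- points$bin_index
    st <- classify_goal(points$mean_systolic, points$mean_diastolic, goal)
    tab$systolic[i] <- sprintf("%d", round_half_up(points$mean_systolic))
    tab$diastolic[i] <- sprintf("%d", round_half_up(points$mean_diastolic))
    tab$bold_systolic[i] <- st$systolic_status != "in_range" | points$is_aggregate
    tab$bold_diastolic[i] <- st$diastolic_status != "in_range" | points$is_aggregate
    tab$gap[i] <- FALSE
  }
  tab
}

stack_annotations <- function(ann, window) {
  empty <- data.frame(date = as.Date(character()), text = character(),
                      n_notes = integer(), index = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(ann) || nrow(ann) == 0L) return(empty)
  d0 <- as.Date(format(window[1], "%Y-%m-%d"))
  d1 <- as.Date(format(window[2], "%Y-%m-%d"))
  keep <- ann$date >= d0 & ann$date <= d1
  ann <- ann[keep, , drop = FALSE]
  if (nrow(ann) == 0L) return(empty)
  # identical dates stack into one marker with concatenated texts
  ann <- ann[order(ann$date), , drop = FALSE]
  by_date <- split(ann$text, format(ann$date))
  out <- data.frame(
    date = as.Date(names(by_date)),
    text = vapply(by_date, paste, character(1), collapse = "; "),
    n_notes = vapply(by_date, length, integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$date), , drop = FALSE]
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

lay_out_medications <- function(meds, window) {
  empty <- data.frame(name = character(), dose = character(),
                      start = as.Date(character()), end = as.Date(character()),
                      ongoing = logical(), lane = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(meds) || nrow(meds) == 0L) return(empty)
  d0 <- as.Date(format(window[1], "%Y-%m-%d"))
  d1 <- as.Date(format(window[2], "%Y-%m-%d"))
  # lanes: one per drug name, ordered by each name's first start date over
  # the FULL course list, so clipping to the window never reassigns lanes
  first <- tapply(as.integer(meds$start), meds$name, min)
  lane_names <- names(sort(first))
  lane_of <- stats::setNames(seq_along(lane_names), lane_names)
  eff_end <- ifelse(is.na(meds$end), as.integer(d1), as.integer(meds$end))
  overlaps <- as.integer(meds$start) <= as.integer(d1) & eff_end >= as.integer(d0)
  meds <- meds[overlaps, , drop = FALSE]
  if (nrow(meds) == 0L) return(empty)
  out <- data.frame(
    name = meds$name, dose = meds$dose,
    start = pmax(meds$start, d0),
    end = pmin(as.Date(ifelse(is.na(meds$end), as.integer(d1),
                              as.integer(meds$end)),
                       origin = "1970-01-01"), d1),
    ongoing = is.na(meds$end),
    lane = as.integer(lane_of[meds$name]),
    stringsAsFactors = FALSE)
  out <- out[order(out$lane, out$start), , drop = FALSE]
  # renumber the lanes actually present, preserving order
  out$lane <- match(out$lane, sort(unique(out$lane)))
  rownames(out) <- NULL
  out
}

#' Resolve data and configuration into a renderer-independent display model
#'
#' Runs the full pipeline — density-schedule selection, binning,
#' aggregation, missing-run segment classification, LOWESS smoothing, data
#' table, goal classification — and attaches the goal bands (each channel's
#' band carries that channel's hue), the annotation track (markers stacked
#' per date) and the medication lanes (one lane per drug name, courses
#' clipped to the window). All panels share one x-domain. The y-axis always
#' contains the goal bands: it spans at least
#' `[min(dbp_low, data) - 5, max(sbp_high, data) + 5]` so the bands can
#' never be autoscaled out of view.
#'
#' A window with measurements but no non-empty bins, or no measurements at
#' all, yields a valid empty-plot model (no points, no segments, all-gap
#' table).
#'
#' @param measurements a `bp_measurements` frame.
#' @param medications optional `bp_medications`.
#' @param annotations optional `bp_annotations`.
#' @param config a [display_config()].
#' @return A `bp_display_model` list with elements `window`, `schedule`,
#'   `config`, `bins`, `points`, `goal_status`, `segments`, `smooth`,
#'   `table`, `annotations`, `medications`, `bands`, `ylim`.
#' @examples
#' ms <- bp_measurements(c("2021-07-03", "2021-07-20", "2021-08-15"),
#'                       c(132, 145, 128), c(84, 92, 79), "home")
#' cfg <- display_config(window = c("2021-07-01", "2021-09-01"))
#' m <- build_display_model(ms, config = cfg)
#' nrow(m$table)  # 62 rows, one per daily bin
#' @export
build_display_model <- function(measurements, medications = NULL,
                                annotations = NULL, config) {
  stopifnot(inherits(config, "bp_display_config"))
  window <- config$window
  schedule <- select_bin_schedule(
    (as.numeric(window[2]) - as.numeric(window[1])) / DAY)
  bins <- make_bins(window[1], window[2], schedule)
  points <- aggregate_measurements(measurements, bins)
  segments <- tryCatch(
    classify_segments(points, nrow(bins), config$missing_threshold),
    bp_no_points = function(e) data.frame(
      from_bin = integer(), to_bin = integer(), gap_bins = integer(),
      style = character(), stringsAsFactors = FALSE))
  smooth <- if (nrow(points) >= 2L) {
    suppressWarnings(smooth_points(points, window[1], config$smoothing))
  } else {
    NULL
  }
  goal <- config$goal
  goal_status <- if (nrow(points) > 0L) {
    cbind(data.frame(bin_index = points$bin_index),
          classify_goal(points$mean_systolic, points$mean_diastolic, goal))
  } else {
    data.frame(bin_index = integer(), systolic_status = character(),
               diastolic_status = character(), stringsAsFactors = FALSE)
  }
  pad <- 5
  data_lo <- if (nrow(points)) min(points$mean_diastolic) else goal$dbp_low
  data_hi <- if (nrow(points)) max(points$mean_systolic) else goal$sbp_high
  structure(list(
    window = window,
    schedule = schedule,
    config = config,
    bins = bins,
    points = points,
    goal_status = goal_status,
    segments = segments,
    smooth = smooth,
    table = build_data_table(points, bins, goal),
    annotations = stack_annotations(annotations, window),
    medications = lay_out_medications(medications, window),
    bands = list(systolic = c(goal$sbp_low, goal$sbp_high),
                 diastolic = c(goal$dbp_low, goal$dbp_high)),
    ylim = c(min(goal$dbp_low, data_lo) - pad,
             max(goal$sbp_high, data_hi) + pad)),
    class = "bp_display_model")
}

#' @export
print.bp_display_model <- function(x, ...) {
  cat(sprintf(
    "BP display model: %s to %s ('%s' schedule, %d bins, %d points, %d gap rows)\n",
    format(x$window[1], "%Y-%m-%d"), format(x$window[2], "%Y-%m-%d"),
    x$schedule$window_label, nrow(x$bins), nrow(x$points), sum(x$table$gap)))
  cat(sprintf("  annotations: %d; medication courses: %d in %d lane(s)\n",
              nrow(x$annotations), nrow(x$medications),
              length(unique(x$medications$lane))))
  invisible(x)
}
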
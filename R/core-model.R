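#' bpdisplay: blood pressure home-monitoring data display engine
#'
#' Turns streams of home/office blood pressure measurements, medication
#' courses and free-text annotations into a linked multi-panel display:
#' a two-line (systolic/diastolic) graph with goal-range bands and a robust
#' LOWESS trend, a value table, an annotation timeline, medication lanes and
#' a scrubber bar. Dense series are first aggregated onto a density schedule
#' that caps any window at 62 displayed points.
#'
#' @section Pipeline:
#' [parse_bp_csv()] / [parse_bp_fhir_bundle()] -> [build_display_model()] ->
#' [render_svg()] / [render_html()]. Synthetic demonstration streams come
#' from [simulate_bp_series()] and [simulate_scenario()].
#'
#' @keywords internal
"_PACKAGE"

# Sources the model accepts. "ambulatory" (24-h ambulatory monitoring) is
# accepted and rendered with the home (circle) symbol; see source_symbol().
BP_SOURCES <- c("home", "office", "inpatient", "other", "ambulatory")

# Physiologic plausibility bounds (mmHg): pressures outside are treated as
# data-entry garbage, not clinical judgment.
BP_BOUNDS <- c(low = 30, high = 300)

as_bp_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) return(as.POSIXct(format(x), tz = "UTC"))
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  # per-element fallback across formats (one bad row must not poison the rest)
  for (f in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out) & !is.na(x))
    if (length(idx) == 0L) break
    out[idx] <- as.POSIXct(strptime(x[idx], f, tz = "UTC"), tz = "UTC")
  }
  out
}

new_bp_measurements <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("bp_measurements", "data.frame")
  df
}

empty_measurements <- function() {
  new_bp_measurements(data.frame(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    systolic = numeric(), diastolic = numeric(),
    source = character(), confirmed = logical()))
}

#' Construct a validated set of blood pressure measurements
#'
#' A measurement is one timestamped systolic/diastolic pair (mmHg) with a
#' source (`home`, `office`, `inpatient`, `other`, or `ambulatory`) and an
#' optional `confirmed` flag (home cuff and technique validated by clinic
#' staff). All invariants are checked; any invalid row is an error. Parsers
#' that must tolerate bad rows use [validate_measurements()] instead.
#'
#' @param timestamp datetimes (`POSIXct`, `Date`, or ISO-8601 strings),
#'   interpreted as timezone-naive local clinic time.
#' @param systolic,diastolic pressures in mmHg; must satisfy
#'   30 <= diastolic < systolic <= 300.
#' @param source measurement source, recycled to length.
#' @param confirmed logical, recycled to length.
#' @return A `bp_measurements` data frame sorted by timestamp.
#' @examples
#' bp_measurements("2021-03-01 08:00", 132, 84, "home")
#' @export
bp_measurements <- function(timestamp, systolic, diastolic,
                            source = "home", confirmed = FALSE) {
  n <- max(length(timestamp), length(systolic), length(diastolic))
  df <- data.frame(
    timestamp = as_bp_time(timestamp),
    systolic = as.numeric(systolic),
    diastolic = as.numeric(diastolic),
    source = rep_len(as.character(source), n),
    confirmed = rep_len(as.logical(confirmed), n))
  v <- validate_measurements(df)
  if (nrow(v$rejects) > 0L) {
    stop("InvalidMeasurement: ", v$rejects$reason[1L],
         " (row ", v$rejects$row[1L], ")", call. = FALSE)
  }
  m <- v$measurements
  new_bp_measurements(m[order(m$timestamp), , drop = FALSE])
}

#' Validate measurement rows, separating accepted rows from rejects
#'
#' Checks every row against the measurement invariants (finite parseable
#' timestamp; known source; 30 <= diastolic < systolic <= 300 mmHg) and
#' splits the input into accepted measurements and a rejects report.
#' `n_input = n_accepted + n_rejected` always; nothing is silently dropped.
#' Validation is idempotent: re-validating accepted rows accepts them all.
#'
#' @param df data frame with columns `timestamp`, `systolic`, `diastolic`,
#'   `source`, and optionally `confirmed`.
#' @param bounds length-2 numeric, physiologic plausibility bounds in mmHg.
#' @return list with `measurements` (a `bp_measurements` frame) and
#'   `rejects` (data frame with `row`, `reason`, and the offending values).
#' @export
validate_measurements <- function(df, bounds = BP_BOUNDS) {
  stopifnot(is.data.frame(df))
  need <- c("timestamp", "systolic", "diastolic", "source")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("MissingColumn: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  ts <- as_bp_time(df$timestamp)
  sbp <- suppressWarnings(as.numeric(df$systolic))
  dbp <- suppressWarnings(as.numeric(df$diastolic))
  src <- as.character(df$source)
  conf <- if ("confirmed" %in% names(df)) {
    as.logical(df$confirmed)
  } else {
    rep(FALSE, n)
  }
  conf[is.na(conf)] <- FALSE

  reason <- rep(NA_character_, n)
  bad_ts <- is.na(ts) | is.infinite(as.numeric(ts))
  reason[bad_ts] <- "unparseable timestamp"
  bad_src <- is.na(reason) & !(src %in% BP_SOURCES)
  reason[bad_src] <- "unknown source"
  bad_num <- is.na(reason) & (is.na(sbp) | is.na(dbp))
  reason[bad_num] <- "non-numeric pressure"
  oob <- is.na(reason) &
    (dbp < bounds[[1]] | sbp > bounds[[2]] | sbp < bounds[[1]] | dbp > bounds[[2]])
  reason[oob] <- "out of physiologic bounds"
  inv <- is.na(reason) & sbp <= dbp
  reason[inv] <- "systolic <= diastolic"

  ok <- is.na(reason)
  rejects <- data.frame(
    row = which(!ok),
    reason = reason[!ok],
    timestamp = as.character(df$timestamp)[!ok],
    systolic = as.character(df$systolic)[!ok],
    diastolic = as.character(df$diastolic)[!ok],
    source = src[!ok],
    stringsAsFactors = FALSE)
  list(
    measurements = new_bp_measurements(data.frame(
      timestamp = ts[ok], systolic = sbp[ok], diastolic = dbp[ok],
      source = src[ok], confirmed = conf[ok])),
    rejects = rejects)
}

#' Per-patient blood pressure goal range
#'
#' Acceptable bounds for each channel, drawn on the display as filled
#' background bands. The shipped default is 90-140 mmHg systolic and
#' 60-90 mmHg diastolic, identical for all patients unless overridden;
#' clinicians may personalise it per patient. The two ranges may overlap
#' numerically.
#'
#' @param sbp_low,sbp_high systolic bounds in mmHg, `sbp_low < sbp_high`.
#' @param dbp_low,dbp_high diastolic bounds in mmHg, `dbp_low < dbp_high`.
#' @return A `bp_goal_range` object.
#' @examples
#' goal_range()             # the shipped default: 90-140 / 60-90
#' goal_range(sbp_high = 130)
#' @export
goal_range <- function(sbp_low = 90, sbp_high = 140,
                       dbp_low = 60, dbp_high = 90) {
  stopifnot(is.numeric(sbp_low), is.numeric(sbp_high),
            is.numeric(dbp_low), is.numeric(dbp_high))
  if (!(sbp_low < sbp_high)) stop("sbp_low must be < sbp_high", call. = FALSE)
  if (!(dbp_low < dbp_high)) stop("dbp_low must be < dbp_high", call. = FALSE)
  structure(list(sbp_low = sbp_low, sbp_high = sbp_high,
                 dbp_low = dbp_low, dbp_high = dbp_high),
            class = "bp_goal_range")
}

#' @export
print.bp_goal_range <- function(x, ...) {
  cat(sprintf("BP goal range: SBP %g-%g mmHg, DBP %g-%g mmHg\n",
              x$sbp_low, x$sbp_high, x$dbp_low, x$dbp_high))
  invisible(x)
}

#' LOWESS smoothing parameters
#'
#' @param frac fraction of points in each local neighbourhood, in (0, 1].
#'   The default 0.30 resolves multi-week trend at the display's point
#'   densities while still averaging over day-to-day noise.
#' @param robust_iterations number of bisquare robustness passes (>= 0);
#'   the default 2 de-emphasises outlier readings, which patients otherwise
#'   over-weight.
#' @param enabled logical; when `FALSE` no smoothing layer is computed and
#'   the raw line renders at full opacity.
#' @return A `bp_smooth_params` object.
#' @export
smooth_params <- function(frac = 0.30, robust_iterations = 2L, enabled = TRUE) {
  stopifnot(is.numeric(frac), length(frac) == 1L, frac > 0, frac <= 1,
            is.numeric(robust_iterations), robust_iterations >= 0,
            is.logical(enabled))
  structure(list(frac = frac,
                 robust_iterations = as.integer(robust_iterations),
                 enabled = enabled),
            class = "bp_smooth_params")
}

is_hex_color <- function(x) {
  is.character(x) && length(x) == 1L && grepl("^#[0-9A-Fa-f]{6}$", x)
}

#' Display configuration
#'
#' Everything needed to resolve raw inputs into a display: the time window,
#' the goal range, the two channel hues of the like-with-like scheme
#' (each channel's points, line and goal band share one hue), the band
#' opacity, the missing-data threshold, and the smoothing parameters.
#'
#' @param window length-2 window (start, end) as datetimes, `Date`s or
#'   ISO-8601 strings; start must precede end.
#' @param goal a [goal_range()].
#' @param systolic_color,diastolic_color 6-digit hex hues. Defaults are the
#'   colorblind-safe pair mint `"#008471"` (systolic) and cocoa `"#9C652B"`
#'   (diastolic).
#' @param band_alpha goal-band fill opacity in (0, 1]; a pastel 0.18 keeps
#'   the bands behind the data.
#' @param missing_threshold fraction of window bins (0, 1): a run of empty
#'   bins longer than this fraction is bridged with a dashed line.
#' @param smoothing a [smooth_params()].
#' @return A `bp_display_config` object.
#' @examples
#' display_config(window = c("2021-07-01", "2021-09-01"))
#' @export
display_config <- function(window,
                           goal = goal_range(),
                           systolic_color = "#008471",
                           diastolic_color = "#9C652B",
                           band_alpha = 0.18,
                           missing_threshold = 0.10,
                           smoothing = smooth_params()) {
  w <- as_bp_time(window)
  if (length(w) != 2L || anyNA(w)) stop("window must be two datetimes", call. = FALSE)
  if (!(w[1] < w[2])) stop("window start must precede end", call. = FALSE)
  if (!is_hex_color(systolic_color) || !is_hex_color(diastolic_color)) {
    stop("colors must be 6-digit hex strings like #008471", call. = FALSE)
  }
  stopifnot(inherits(goal, "bp_goal_range"), inherits(smoothing, "bp_smooth_params"),
            band_alpha > 0, band_alpha <= 1,
            missing_threshold > 0, missing_threshold < 1)
  structure(list(window = w, goal = goal,
                 systolic_color = systolic_color,
                 diastolic_color = diastolic_color,
                 band_alpha = band_alpha,
                 missing_threshold = missing_threshold,
                 smoothing = smoothing),
            class = "bp_display_config")
}

#' Read a display configuration from a key/value YAML file
#'
#' Schema (all keys optional except `window`):
#' ```yaml
#' window: {start: 2021-07-01, end: 2021-09-01}
#' goal:   {sbp_low: 90, sbp_high: 140, dbp_low: 60, dbp_high: 90}
#' colors: {systolic: "#008471", diastolic: "#9C652B"}
#' band_alpha: 0.18
#' missing_threshold: 0.10
#' smoothing: {enabled: true, frac: 0.30, robust_iterations: 2}
#' ```
#' Omitted keys take the shipped defaults above.
#'
#' @param path path to a YAML config file.
#' @return A [display_config()] object.
#' @export
read_display_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$window)) stop("config must define window.start and window.end",
                              call. = FALSE)
  g <- y$goal
  goal <- goal_range(
    sbp_low = g$sbp_low %||% 90, sbp_high = g$sbp_high %||% 140,
    dbp_low = g$dbp_low %||% 60, dbp_high = g$dbp_high %||% 90)
  s <- y$smoothing
  sm <- smooth_params(
    frac = s$frac %||% 0.30,
    robust_iterations = s$robust_iterations %||% 2L,
    enabled = s$enabled %||% TRUE)
  display_config(
    window = c(y$window$start, y$window$end),
    goal = goal,
    systolic_color = y$colors$systolic %||% "#008471",
    diastolic_color = y$colors$diastolic %||% "#9C652B",
    band_alpha = y$band_alpha %||% 0.18,
    missing_threshold = y$missing_threshold %||% 0.10,
    smoothing = sm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Medication courses
#'
#' One row per drug/dose interval. A dose change is represented as two
#' adjacent courses of the same drug (e.g. lisinopril 10 mg then 20 mg);
#' an open `end` means the course is ongoing.
#'
#' @param name drug name(s).
#' @param dose dose text (e.g. `"10 mg daily"`).
#' @param start,end course dates (`Date` or ISO strings); `end` may be `NA`
#'   for an ongoing course, otherwise `start <= end`.
#' @return A `bp_medications` data frame sorted by (name, start).
#' @export
medication_courses <- function(name, dose, start, end = NA) {
  n <- max(length(name), length(start))
  start <- as.Date(start)
  end <- as.Date(rep_len(end, n))
  if (anyNA(start)) stop("UnparseableDate: missing/invalid start", call. = FALSE)
  bad <- !is.na(end) & end < start
  if (any(bad)) stop("InvalidCourse: end before start", call. = FALSE)
  df <- data.frame(name = rep_len(as.character(name), n),
                   dose = rep_len(as.character(dose), n),
                   start = start, end = end, stringsAsFactors = FALSE)
  df <- df[order(df$name, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("bp_medications", "data.frame")
  df
}

#' Dated free-text annotations
#'
#' A user (patient or provider) records only a date and the annotation text;
#' the display places a marker on the x-axis at that date.
#'
#' @param date annotation dates.
#' @param text non-empty annotation texts.
#' @param author_role `"patient"` or `"provider"`, recycled.
#' @return A `bp_annotations` data frame sorted by date.
#' @export
bp_annotations <- function(date, text, author_role = "patient") {
  date <- as.Date(date)
  text <- as.character(text)
  if (anyNA(date)) stop("UnparseableDate: invalid annotation date", call. = FALSE)
  if (any(is.na(text) | !nzchar(trimws(text)))) {
    stop("annotation text must be non-empty", call. = FALSE)
  }
  role <- rep_len(match.arg(author_role, c("patient", "provider"),
                            several.ok = TRUE), length(date))
  df <- data.frame(date = date, text = text, author_role = role,
                   stringsAsFactors = FALSE)
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("bp_annotations", "data.frame")
  df
}

#' Plot symbol for a measurement source
#'
#' The final design uses only two symbols: circles for home measurements and
#' squares for office measurements. Ambulatory (24-h) readings are mapped to
#' the home symbol; inpatient and other clinical sources to the office
#' symbol, since their provenance is clinical rather than self-measured.
#'
#' @param source character vector of sources.
#' @return `"circle_home"` or `"square_office"` per element.
#' @export
source_symbol <- function(source) {
  ifelse(source %in% c("home", "ambulatory"), "circle_home", "square_office")
}
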
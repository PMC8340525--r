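fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

df_cols <- function(df, time_cols = character(), date_cols = character()) {
  out <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (nm %in% time_cols) v <- fmt_time(v)
    if (nm %in% date_cols) v <- format(v)
    out[[nm]] <- v
  }
  out
}

col_as <- function(x, what) {
  x <- unlist(x)
  switch(what,
         time = {
           out <- as.POSIXct(as.character(x), tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%S")
           if (length(x) == 0L) as.POSIXct(character(), tz = "UTC") else out
         },
         date = as.Date(as.character(x)),
         num = as.numeric(x),
         int = as.integer(x),
         chr = as.character(x),
         lgl = as.logical(x))
}

cols_df <- function(lst, types, klass = NULL) {
  cols <- lapply(names(types), function(nm) col_as(lst[[nm]], types[[nm]]))
  names(cols) <- names(types)
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df <- df[0, , drop = FALSE]
  }
  rownames(df) <- NULL
  if (!is.null(klass)) class(df) <- c(klass, "data.frame")
  df
}

#' Serialize a display model to JSON (and back)
#'
#' A documented, loss-free JSON form of the resolved display model, with a
#' stable key order so outputs diff cleanly. `read_display_json()` inverts
#' it exactly: every panel's contents round-trip.
#'
#' @param model a `bp_display_model` from [build_display_model()].
#' @return `write_display_json()`: a JSON string.
#' @export
write_display_json <- function(model) {
  stopifnot(inherits(model, "bp_display_model"))
  cfg <- model$config
  doc <- list(
    format = "bp-display-model",
    version = 1L,
    window = list(start = fmt_time(model$window[1]),
                  end = fmt_time(model$window[2])),
    schedule = list(window_label = model$schedule$window_label,
                    bin_seconds = model$schedule$bin_seconds,
                    max_points = model$schedule$max_points),
    config = list(
      goal = unclass(cfg$goal),
      systolic_color = cfg$systolic_color,
      diastolic_color = cfg$diastolic_color,
      band_alpha = cfg$band_alpha,
      missing_threshold = cfg$missing_threshold,
      smoothing = unclass(cfg$smoothing)),
    bins = df_cols(model$bins, time_cols = c("start", "end")),
    points = df_cols(model$points, time_cols = c("start", "end")),
    goal_status = df_cols(model$goal_status),
    segments = df_cols(model$segments),
    smooth = if (is.null(model$smooth)) NULL else df_cols(model$smooth),
    table = df_cols(model$table),
    annotations = df_cols(model$annotations, date_cols = "date"),
    medications = df_cols(model$medications, date_cols = c("start", "end")),
    bands = model$bands,
    ylim = model$ylim)
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null", pretty = TRUE)
}

#' @rdname write_display_json
#' @param json JSON text (or a file path) produced by
#'   `write_display_json()`.
#' @return `read_display_json()`: the reconstructed `bp_display_model`.
#' @export
read_display_json <- function(json) {
  txt <- if (length(json) == 1L && !grepl("^[[:space:]]*[{]", json) &&
             file.exists(json)) {
    paste(readLines(json, warn = FALSE), collapse = "\n")
  } else {
    paste(json, collapse = "\n")
  }
  d <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!identical(d$format, "bp-display-model")) {
    stop("not a bp-display-model document", call. = FALSE)
  }
  g <- d$config$goal
  s <- d$config$smoothing
  config <- display_config(
    window = c(d$window$start, d$window$end),
    goal = goal_range(g$sbp_low, g$sbp_high, g$dbp_low, g$dbp_high),
    systolic_color = d$config$systolic_color,
    diastolic_color = d$config$diastolic_color,
    band_alpha = d$config$band_alpha,
    missing_threshold = d$config$missing_threshold,
    smoothing = smooth_params(s$frac, s$robust_iterations, s$enabled))
  structure(list(
    window = as_bp_time(c(d$window$start, d$window$end)),
    schedule = structure(list(window_label = d$schedule$window_label,
                              bin_seconds = as.numeric(d$schedule$bin_seconds),
                              max_points = as.integer(d$schedule$max_points)),
                         class = "bp_bin_schedule"),
    config = config,
    bins = cols_df(d$bins, c(bin_index = "int", start = "time", end = "time")),
    points = cols_df(d$points,
                     c(bin_index = "int", start = "time", end = "time",
                       mean_systolic = "num", mean_diastolic = "num",
                       n_measurements = "int", source_symbol = "chr",
                       is_aggregate = "lgl"),
                     klass = "bp_aggregated"),
    goal_status = cols_df(d$goal_status,
                          c(bin_index = "int", systolic_status = "chr",
                            diastolic_status = "chr")),
    segments = cols_df(d$segments,
                       c(from_bin = "int", to_bin = "int",
                         gap_bins = "int", style = "chr")),
    smooth = if (is.null(d$smooth)) NULL else
      cols_df(d$smooth, c(bin_index = "int", x_days = "num",
                          systolic = "num", diastolic = "num")),
    table = cols_df(d$table,
                    c(bin_index = "int", label = "chr", systolic = "chr",
                      diastolic = "chr", bold_systolic = "lgl",
                      bold_diastolic = "lgl", gap = "lgl")),
    annotations = cols_df(d$annotations,
                          c(date = "date", text = "chr", n_notes = "int",
                            index = "int")),
    medications = cols_df(d$medications,
                          c(name = "chr", dose = "chr", start = "date",
                            end = "date", ongoing = "lgl", lane = "int")),
    bands = list(systolic = as.numeric(unlist(d$bands$systolic)),
                 diastolic = as.numeric(unlist(d$bands$diastolic))),
    ylim = as.numeric(unlist(d$ylim))),
    class = "bp_display_model")
}
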
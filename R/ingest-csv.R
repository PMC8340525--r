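read_csv_input <- function(file = NULL, text = NULL) {
  if (is.null(file) && is.null(text)) stop("give file or text", call. = FALSE)
  df <- tryCatch(
    if (!is.null(text)) {
      utils::read.csv(text = text, stringsAsFactors = FALSE,
                      colClasses = "character", check.names = FALSE)
    } else {
      utils::read.csv(file, stringsAsFactors = FALSE,
                      colClasses = "character", check.names = FALSE)
    },
    error = function(e) stop("EmptyFile: ", conditionMessage(e), call. = FALSE))
  names(df) <- trimws(names(df))
  df
}

#' Parse blood pressure measurements from CSV
#'
#' Reads an RFC 4180 CSV (UTF-8, ISO-8601 timestamps) with header columns
#' `timestamp`, `systolic`, `diastolic`, `source` and optionally
#' `confirmed`; other column names can be remapped via `column_map`. Every
#' row is validated; rows that fail validation are collected into a rejects
#' report rather than silently dropped, so
#' `n rows = n accepted + n rejected`. Accepted measurements are sorted
#' ascending by timestamp; duplicate (timestamp, source) pairs collapse to
#' the last occurrence (home cuffs can re-transmit), with a message noting
#' how many were collapsed.
#'
#' @param file path or connection to a CSV file.
#' @param text CSV content as a single string (alternative to `file`).
#' @param column_map named character vector mapping the canonical names
#'   (`timestamp`, `systolic`, ...) to the file's column names.
#' @return list with `measurements` (`bp_measurements`), `rejects` (rejects
#'   report data frame) and `n_duplicates_collapsed`.
#' @examples
#' r <- parse_bp_csv(text = paste(
#'   "timestamp,systolic,diastolic,source",
#'   "2021-03-01T08:00:00,132,84,home",
#'   "2021-03-02T08:00:00,128,80,home", sep = "\n"))
#' nrow(r$measurements)
#' @export
parse_bp_csv <- function(file = NULL, text = NULL,
                         column_map = c(timestamp = "timestamp",
                                        systolic = "systolic",
                                        diastolic = "diastolic",
                                        source = "source",
                                        confirmed = "confirmed")) {
  df <- read_csv_input(file, text)
  if (nrow(df) == 0L && ncol(df) == 0L) stop("EmptyFile", call. = FALSE)
  need <- c("timestamp", "systolic", "diastolic", "source")
  for (canon in need) {
    col <- if (canon %in% names(column_map)) column_map[[canon]] else canon
    if (!col %in% names(df)) {
      stop("MissingColumn: ", col, call. = FALSE)
    }
  }
  get_col <- function(canon, default = NULL) {
    col <- if (canon %in% names(column_map)) column_map[[canon]] else canon
    if (col %in% names(df)) df[[col]] else default
  }
  raw <- data.frame(
    timestamp = get_col("timestamp"),
    systolic = get_col("systolic"),
    diastolic = get_col("diastolic"),
    source = trimws(get_col("source")),
    confirmed = tolower(trimws(get_col("confirmed",
                                       rep("false", nrow(df))))) %in%
      c("true", "t", "1", "yes"),
    stringsAsFactors = FALSE)
  v <- validate_measurements(raw)
  m <- v$measurements
  m <- m[order(m$timestamp), , drop = FALSE]
  key <- paste(format(m$timestamp, "%Y-%m-%dT%H:%M:%S"), m$source)
  dup <- duplicated(key, fromLast = TRUE)  # last wins
  if (any(dup)) {
    message(sum(dup), " duplicate (timestamp, source) row(s) collapsed; last wins")
  }
  m <- new_bp_measurements(m[!dup, , drop = FALSE])
  list(measurements = m, rejects = v$rejects,
       n_duplicates_collapsed = sum(dup))
}

#' Parse medication courses from CSV
#'
#' Columns `name`, `dose`, `start`, `end`; a blank `end` means the course is
#' ongoing. Courses are sorted by (name, start); overlapping same-name
#' courses are allowed — a dose change appears as adjacent courses.
#' Rows with unparseable dates or `end` before `start` go to the rejects
#' report, preserving `n rows = n accepted + n rejected`.
#'
#' @inheritParams parse_bp_csv
#' @return list with `medications` (`bp_medications`) and `rejects`.
#' @export
parse_medications <- function(file = NULL, text = NULL) {
  df <- read_csv_input(file, text)
  if (nrow(df) == 0L && ncol(df) == 0L) {
    return(list(medications = medication_courses(character(), character(),
                                                 as.Date(character())),
                rejects = data.frame(row = integer(), reason = character())))
  }
  need <- c("name", "dose", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("MissingColumn: ", paste(miss, collapse = ", "),
                              call. = FALSE)
  start <- suppressWarnings(as.Date(trimws(df$start)))
  end_raw <- trimws(df$end)
  end <- suppressWarnings(as.Date(ifelse(nzchar(end_raw), end_raw, NA)))
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(start)] <- "unparseable start date"
  reason[is.na(reason) & nzchar(end_raw) & is.na(end)] <- "unparseable end date"
  reason[is.na(reason) & !is.na(end) & end < start] <- "end before start"
  reason[is.na(reason) & !nzchar(trimws(df$name))] <- "empty name"
  ok <- is.na(reason)
  meds <- medication_courses(df$name[ok], df$dose[ok], start[ok], end[ok])
  rejects <- data.frame(row = which(!ok), reason = reason[!ok],
                        name = df$name[!ok], start = df$start[!ok],
                        end = df$end[!ok], stringsAsFactors = FALSE)
  list(medications = meds, rejects = rejects)
}

#' Parse dated annotations from CSV
#'
#' Columns `date`, `text`, and optionally `author_role`
#' (`patient`/`provider`, default `patient`). Empty texts and bad dates are
#' rejected with a reason.
#'
#' @inheritParams parse_bp_csv
#' @return list with `annotations` (`bp_annotations`) and `rejects`.
#' @export
parse_annotations <- function(file = NULL, text = NULL) {
  df <- read_csv_input(file, text)
  if (nrow(df) == 0L && ncol(df) == 0L) {
    return(list(annotations = bp_annotations(as.Date(character()), character()),
                rejects = data.frame(row = integer(), reason = character())))
  }
  miss <- setdiff(c("date", "text"), names(df))
  if (length(miss) > 0L) stop("MissingColumn: ", paste(miss, collapse = ", "),
                              call. = FALSE)
  date <- suppressWarnings(as.Date(trimws(df$date)))
  role <- if ("author_role" %in% names(df)) trimws(df$author_role) else "patient"
  role <- rep_len(role, nrow(df))
  role[!role %in% c("patient", "provider")] <- "patient"
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(date)] <- "unparseable date"
  reason[is.na(reason) & !nzchar(trimws(df$text))] <- "empty text"
  ok <- is.na(reason)
  ann <- bp_annotations(date[ok], df$text[ok], role[ok])
  rejects <- data.frame(row = which(!ok), reason = reason[!ok],
                        date = df$date[!ok], stringsAsFactors = FALSE)
  list(annotations = ann, rejects = rejects)
}

#' Write measurement / medication / annotation tables as CSV
#'
#' Writers for the same CSV dialects the parsers read, so generated or
#' aggregated data round-trips losslessly.
#'
#' @param x the object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bp_csv <- function(x, path) {
  stopifnot(inherits(x, "bp_measurements"))
  out <- data.frame(timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%S"),
                    systolic = x$systolic, diastolic = x$diastolic,
                    source = x$source,
                    confirmed = tolower(as.character(x$confirmed)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bp_csv
#' @export
write_medications_csv <- function(x, path) {
  stopifnot(inherits(x, "bp_medications"))
  out <- data.frame(name = x$name, dose = x$dose,
                    start = format(x$start),
                    end = ifelse(is.na(x$end), "", format(x$end)))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_bp_csv
#' @export
write_annotations_csv <- function(x, path) {
  stopifnot(inherits(x, "bp_annotations"))
  out <- data.frame(date = format(x$date), text = x$text,
                    author_role = x$author_role)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_bp_csv
#' @export
write_rejects_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
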
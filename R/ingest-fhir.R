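# LOINC codes identifying a blood pressure panel Observation and its
# systolic/diastolic components (FHIR R4 vital-signs profile).
LOINC_BP_PANEL <- "85354-9"
LOINC_SBP <- "8480-6"
LOINC_DBP <- "8462-4"

coding_codes <- function(codeable) {
  if (is.null(codeable)) return(character())
  codings <- codeable$coding
  if (is.null(codings)) return(character())
  vapply(codings, function(cd) as.character(cd$code %||% NA_character_),
         character(1))
}

# Source mapping, in priority order:
#   1. an Observation extension whose url ends in "measurement-source",
#      with valueCode in {home, office, inpatient, other, ambulatory};
#   2. any code.coding or category coding literally equal to one of those
#      tokens;
#   3. default "office" (clinic-origin is the conservative assumption).
fhir_source <- function(res) {
  for (ext in res$extension %||% list()) {
    url <- as.character(ext$url %||% "")
    if (grepl("measurement-source$", url)) {
      v <- as.character(ext$valueCode %||% "")
      if (v %in% BP_SOURCES) return(v)
    }
  }
  toks <- c(coding_codes(res$code),
            unlist(lapply(res$category %||% list(), coding_codes)))
  hit <- toks[toks %in% BP_SOURCES]
  if (length(hit) > 0L) return(hit[[1]])
  "office"
}

#' Parse blood pressure measurements from a FHIR R4 Bundle
#'
#' Walks a FHIR Bundle of Observation resources and extracts blood pressure
#' panels: Observations whose code contains LOINC 85354-9, with component
#' codes 8480-6 (systolic) and 8462-4 (diastolic). Non-BP Observations
#' (heart rate, weight, ...) are ignored. A panel missing a component, a
#' timestamp, or failing measurement validation goes to the rejects report,
#' so `n BP panels = n accepted + n rejected`. The measurement source is
#' derived from an Observation extension whose url ends in
#' `measurement-source` (valueCode `home`/`office`/`inpatient`/`other`/
#' `ambulatory`), else from a matching coding token, else defaults to
#' `office`; a `home-confirmed` extension (valueBoolean) sets the
#' `confirmed` flag, which otherwise defaults to unconfirmed.
#'
#' @param json FHIR Bundle JSON, as a string or a file path.
#' @return list with `measurements` (`bp_measurements`, sorted ascending)
#'   and `rejects`.
#' @export
parse_bp_fhir_bundle <- function(json) {
  txt <- if (length(json) == 1L && !grepl("[{\\[]", substr(json, 1, 1)) &&
             file.exists(json)) {
    paste(readLines(json, warn = FALSE), collapse = "\n")
  } else {
    paste(json, collapse = "\n")
  }
  b <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                error = function(e) stop("NotABundle: invalid JSON: ",
                                         conditionMessage(e), call. = FALSE))
  if (!identical(b$resourceType, "Bundle")) {
    stop("NotABundle: resourceType is not 'Bundle'", call. = FALSE)
  }
  rows <- list()
  rejects <- list()
  panel_i <- 0L
  for (entry in b$entry %||% list()) {
    res <- entry$resource
    if (is.null(res) || !is.list(res)) next
    if (!identical(res$resourceType, "Observation")) next
    if (!LOINC_BP_PANEL %in% coding_codes(res$code)) next
    panel_i <- panel_i + 1L
    sbp <- dbp <- NA_real_
    for (comp in res$component %||% list()) {
      codes <- coding_codes(comp$code)
      val <- comp$valueQuantity$value
      if (LOINC_SBP %in% codes && !is.null(val)) sbp <- as.numeric(val)
      if (LOINC_DBP %in% codes && !is.null(val)) dbp <- as.numeric(val)
    }
    ts <- res$effectiveDateTime %||% res$effectivePeriod$start %||% NA_character_
    confirmed <- FALSE
    for (ext in res$extension %||% list()) {
      if (grepl("home-confirmed$", as.character(ext$url %||% ""))) {
        confirmed <- isTRUE(ext$valueBoolean)
      }
    }
    if (is.na(sbp) || is.na(dbp)) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        panel = panel_i, reason = "incomplete panel (missing component)",
        timestamp = as.character(ts), stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      panel = panel_i, timestamp = as.character(ts), systolic = sbp,
      diastolic = dbp, source = fhir_source(res), confirmed = confirmed,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(list(measurements = empty_measurements(),
                rejects = if (length(rejects)) do.call(rbind, rejects)
                          else data.frame(panel = integer(),
                                          reason = character())))
  }
  raw <- do.call(rbind, rows)
  v <- validate_measurements(raw[, -1, drop = FALSE])
  if (nrow(v$rejects) > 0L) {
    v$rejects$reason <- paste("malformed observation:", v$rejects$reason)
    more <- data.frame(panel = raw$panel[v$rejects$row],
                       reason = v$rejects$reason,
                       timestamp = v$rejects$timestamp,
                       stringsAsFactors = FALSE)
    rejects <- c(rejects, list(more))
  }
  m <- v$measurements
  m <- new_bp_measurements(m[order(m$timestamp), , drop = FALSE])
  list(measurements = m,
       rejects = if (length(rejects)) do.call(rbind, rejects)
                 else data.frame(panel = integer(), reason = character()))
}
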
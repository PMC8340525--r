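# Small in-code fixtures shared across test files.

demo_measurements <- function() {
  bp_measurements(
    timestamp = c("2021-07-03 08:00", "2021-07-20 08:00", "2021-08-15 08:00"),
    systolic = c(132, 145, 128),
    diastolic = c(84, 92, 79),
    source = c("home", "office", "home"))
}

demo_config <- function(...) {
  display_config(window = c("2021-07-01", "2021-09-01"), ...)
}

# Measurements placed in specific daily bins of the Jul 1 - Sep 1 window.
measurements_in_bins <- function(bins_occupied, sbp = 120, dbp = 80,
                                 source = "home") {
  ts <- as.POSIXct("2021-07-01 09:00:00", tz = "UTC") +
    (bins_occupied - 1) * 86400
  bp_measurements(ts, rep_len(sbp, length(ts)), rep_len(dbp, length(ts)),
                  rep_len(source, length(ts)))
}

# FHIR bundle fixture built from R lists; obs_list entries are resources.
fhir_bundle_json <- function(obs_list) {
  jsonlite::toJSON(list(
    resourceType = "Bundle",
    type = "collection",
    entry = lapply(obs_list, function(r) list(resource = r))),
    auto_unbox = TRUE)
}

fhir_bp_obs <- function(time, sbp = 132, dbp = 84, source = NULL,
                        drop_component = NULL) {
  comps <- list(
    list(code = list(coding = list(list(system = "http://loinc.org",
                                        code = "8480-6"))),
         valueQuantity = list(value = sbp, unit = "mmHg")),
    list(code = list(coding = list(list(system = "http://loinc.org",
                                        code = "8462-4"))),
         valueQuantity = list(value = dbp, unit = "mmHg")))
  if (!is.null(drop_component)) comps <- comps[-drop_component]
  res <- list(
    resourceType = "Observation",
    status = "final",
    code = list(coding = list(list(system = "http://loinc.org",
                                   code = "85354-9"))),
    effectiveDateTime = time,
    component = comps)
  if (!is.null(source)) {
    res$extension <- list(list(
      url = "https://example.org/fhir/StructureDefinition/measurement-source",
      valueCode = source))
  }
  res
}

fhir_hr_obs <- function(time, rate = 72) {
  list(resourceType = "Observation", status = "final",
       code = list(coding = list(list(system = "http://loinc.org",
                                      code = "8867-4"))),
       effectiveDateTime = time,
       valueQuantity = list(value = rate, unit = "beats/min"))
}
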
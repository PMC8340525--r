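Package: bpdisplay
Title: Blood Pressure Home-Monitoring Data Display Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rendering engine for longitudinal blood pressure data shared by
    patients and clinicians during hypertension care. Ingests home and office
    measurements (CSV or FHIR R4 Observation bundles), medication courses and
    free-text annotations; aggregates dense series onto a fixed density
    schedule (at most 62 displayed points for any window); smooths the
    aggregated trend with robust LOWESS; classifies values against per-patient
    goal ranges; and renders the linked multi-panel display (line graph with
    goal-range bands, data table, annotation timeline, medication lanes,
    scrubber bar) as deterministic static SVG or self-contained interactive
    HTML. Includes a seeded synthetic generator of home-monitoring streams
    (circadian rhythm, AR(1) drift, white-coat offset, medication response,
    outliers, missing runs) for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
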
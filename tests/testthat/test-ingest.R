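bp_csv <- function(rows) {
  paste(c("timestamp,systolic,diastolic,source", rows), collapse = "\n")
}

test_that("CSV parsing preserves counts, validates rows, and sorts output", {
  r <- parse_bp_csv(text = bp_csv(c(
    "2021-03-01T08:00:00,132,84,home",
    "2021-03-02T08:00:00,128,80,home",
    "2021-03-03T08:00:00,140,88,office")))
  expect_equal(nrow(r$measurements), 3L)
  expect_equal(nrow(r$rejects), 0L)

  r <- parse_bp_csv(text = bp_csv(c(
    "2021-03-01T08:00:00,132,84,home",
    "2021-03-02T08:00:00,80,128,home",
    "2021-03-03T08:00:00,140,88,office")))
  expect_equal(nrow(r$measurements), 2L)
  expect_equal(r$rejects$reason, "systolic <= diastolic")

  r <- parse_bp_csv(text = bp_csv(c(
    "2021-03-05T08:00:00,132,84,home",
    "2021-03-01T08:00:00,128,80,home",
    "2021-03-03T08:00:00,140,88,office")))
  expect_false(is.unsorted(r$measurements$timestamp))
})

test_that("no silent loss: rows always split into accepted plus rejects", {
  set.seed(11)
  for (k in 1:5) {
    n <- sample(3:12, 1)
    sbp <- sample(c(60:200, 400), n, replace = TRUE)
    dbp <- sample(40:220, n, replace = TRUE)
    rows <- sprintf("2021-03-%02dT08:00:00,%d,%d,home", seq_len(n), sbp, dbp)
    r <- parse_bp_csv(text = bp_csv(rows))
    expect_equal(nrow(r$measurements) + nrow(r$rejects), n)
  }
})

test_that("duplicate (timestamp, source) rows collapse to the last occurrence", {
  r <- suppressMessages(parse_bp_csv(text = bp_csv(c(
    "2021-03-01T08:00:00,132,84,home",
    "2021-03-01T08:00:00,120,80,home",
    "2021-03-01T08:00:00,125,82,office"))))
  expect_equal(nrow(r$measurements), 2L)
  expect_equal(r$n_duplicates_collapsed, 1L)
  home <- r$measurements[r$measurements$source == "home", ]
  expect_equal(home$systolic, 120)  # last wins
})

test_that("CSV parsing errors on structural problems and honours column_map", {
  expect_error(parse_bp_csv(text = "timestamp,systolic,source\n2021-03-01,120,home"),
               "MissingColumn")
  expect_error(parse_bp_csv(text = ""), "EmptyFile")
  r <- parse_bp_csv(
    text = "time,sys,dia,src\n2021-03-01T08:00:00,132,84,home",
    column_map = c(timestamp = "time", systolic = "sys",
                   diastolic = "dia", source = "src"))
  expect_equal(r$measurements$systolic, 132)
})

test_that("measurement CSVs written by the package re-parse losslessly", {
  s <- simulate_bp_series(sim_params(seed = 3), c("2021-07-01", "2021-07-15"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_bp_csv(s, path)
  r <- parse_bp_csv(path)
  expect_equal(nrow(r$rejects), 0L)
  expect_equal(r$measurements$timestamp, s$timestamp)
  expect_equal(r$measurements$systolic, s$systolic, tolerance = 1e-9)
  expect_equal(r$measurements$source, s$source)
})

test_that("medication CSVs parse into sorted courses with a rejects report", {
  txt <- paste(
    "name,dose,start,end",
    "Lisinopril,20 mg daily,2021-03-01,",
    "Lisinopril,10 mg daily,2021-01-05,2021-03-01",
    sep = "\n")
  r <- parse_medications(text = txt)
  expect_equal(nrow(r$medications), 2L)
  # sorted by (name, start): dose change is two adjacent courses
  expect_equal(r$medications$dose, c("10 mg daily", "20 mg daily"))
  expect_true(is.na(r$medications$end[2]))  # ongoing

  r <- parse_medications(text = "name,dose,start,end\nX,1 mg,2021-05-01,2021-04-01")
  expect_equal(nrow(r$medications), 0L)
  expect_equal(r$rejects$reason, "end before start")

  r <- parse_medications(text = "name,dose,start,end")
  expect_equal(nrow(r$medications), 0L)
  expect_equal(nrow(r$rejects), 0L)
})

test_that("annotation CSVs reject empty texts and keep the rest", {
  txt <- paste("date,text,author_role",
               "2021-03-15,Started low-sodium diet,patient",
               "2021-04-01,,provider",
               sep = "\n")
  r <- parse_annotations(text = txt)
  expect_equal(nrow(r$annotations), 1L)
  expect_equal(r$rejects$reason, "empty text")
})

test_that("FHIR bundles yield one measurement per complete BP panel", {
  j <- fhir_bundle_json(list(fhir_bp_obs("2021-03-01T08:00:00", 132, 84,
                                         source = "home")))
  r <- parse_bp_fhir_bundle(j)
  expect_equal(nrow(r$measurements), 1L)
  expect_equal(r$measurements$systolic, 132)
  expect_equal(r$measurements$source, "home")

  # non-BP observations are filtered by panel code, not rejected
  j <- fhir_bundle_json(list(
    fhir_bp_obs("2021-03-01T08:00:00", 132, 84, source = "home"),
    fhir_hr_obs("2021-03-01T08:05:00"),
    fhir_bp_obs("2021-03-02T09:00:00", 141, 90)))
  r <- parse_bp_fhir_bundle(j)
  expect_equal(nrow(r$measurements), 2L)
  expect_equal(nrow(r$rejects), 0L)
  expect_equal(r$measurements$source, c("home", "office"))  # default office

  # incomplete panel: missing diastolic component
  j <- fhir_bundle_json(list(
    fhir_bp_obs("2021-03-01T08:00:00", drop_component = 2)))
  r <- parse_bp_fhir_bundle(j)
  expect_equal(nrow(r$measurements), 0L)
  expect_match(r$rejects$reason, "incomplete panel")
})

test_that("FHIR parsing rejects non-bundles and malformed panels", {
  expect_error(parse_bp_fhir_bundle('{"resourceType":"Observation"}'),
               "NotABundle")
  expect_error(parse_bp_fhir_bundle("not json"), "NotABundle")
  j <- fhir_bundle_json(list(fhir_bp_obs("2021-03-01T08:00:00", 80, 120)))
  r <- parse_bp_fhir_bundle(j)
  expect_equal(nrow(r$measurements), 0L)
  expect_match(r$rejects$reason, "malformed observation")
})

test_that("display-model JSON round-trips every panel losslessly", {
  scn <- simulate_scenario("nascence", seed = 5)
  cfg <- display_config(window = scn$window)
  model <- build_display_model(scn$measurements, scn$medications,
                               scn$annotations, cfg)
  j <- write_display_json(model)
  back <- read_display_json(j)
  for (part in c("window", "bins", "points", "goal_status", "segments",
                 "smooth", "table", "annotations", "medications", "bands",
                 "ylim")) {
    expect_equal(back[[part]], model[[part]], info = part)
  }
  expect_equal(back$config$goal, model$config$goal)
  expect_equal(back$schedule$window_label, model$schedule$window_label)
  # stable output: serializing the reconstruction reproduces the bytes
  expect_identical(write_display_json(back), j)
})

test_that("display-model JSON handles an empty model and lists every point", {
  cfg <- demo_config()
  empty <- build_display_model(
    bp_measurements(character(), numeric(), numeric()), config = cfg)
  j <- write_display_json(empty)
  back <- read_display_json(j)
  expect_equal(nrow(back$points), 0L)
  expect_equal(nrow(back$table), 62L)

  dense <- simulate_bp_series(sim_params(seed = 2, cadence_minutes = 360),
                              c("2021-07-01", "2021-09-01"))
  model <- build_display_model(dense, config = cfg)
  expect_equal(nrow(model$points), 62L)
  doc <- jsonlite::fromJSON(write_display_json(model))
  expect_length(doc$points$bin_index, 62L)
})
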
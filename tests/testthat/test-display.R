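test_that("goal classification is per channel with inclusive bounds", {
  g <- goal_range()
  expect_equal(unlist(classify_goal(120, 75, g)),
               c(systolic_status = "in_range", diastolic_status = "in_range"))
  expect_equal(classify_goal(150, 75, g)$systolic_status, "above")
  expect_equal(classify_goal(85, 55, g)$systolic_status, "below")
  expect_equal(classify_goal(85, 55, g)$diastolic_status, "below")
  # boundary values are in range (inclusive bounds)
  expect_equal(unlist(classify_goal(140, 90, g)),
               c(systolic_status = "in_range", diastolic_status = "in_range"))
  expect_equal(unlist(classify_goal(90, 60, g)),
               c(systolic_status = "in_range", diastolic_status = "in_range"))
})

test_that("data table rows mirror bins: gaps, bold rules, half-up rounding", {
  bins <- make_bins("2021-07-01", "2021-09-01")
  ms <- bp_measurements(
    c("2021-07-01 08:00",                      # out of range both channels
      "2021-07-03 08:00", "2021-07-03 12:00", "2021-07-03 20:00",  # n=3 in range
      "2021-07-05 08:00"),                     # in range, single
    c(150, 118, 119, 120, 120.5),
    c(95, 76, 77, 78, 79.5))
  pts <- aggregate_measurements(ms, bins)
  tab <- build_data_table(pts, bins, goal_range())
  expect_equal(nrow(tab), 62L)
  expect_equal(sum(tab$gap), 59L)
  expect_equal(tab$systolic[tab$gap][1], "—")  # em-dash placeholder

  r1 <- tab[tab$bin_index == 1, ]          # 150/95: bold by range
  expect_true(r1$bold_systolic && r1$bold_diastolic)
  r3 <- tab[tab$bin_index == 3, ]          # in-range aggregate of 3: bold
  expect_true(r3$bold_systolic && r3$bold_diastolic)
  expect_equal(r3$systolic, "119")         # rounded mean
  r5 <- tab[tab$bin_index == 5, ]          # single in-range: plain, half-up
  expect_false(r5$bold_systolic || r5$bold_diastolic)
  expect_equal(r5$systolic, "121")         # 120.5 rounds half-up
  expect_equal(r5$diastolic, "80")
})

test_that("the resolved model links all panels over one window", {
  ms <- demo_measurements()
  meds <- medication_courses(
    c("Lisinopril", "Lisinopril"), c("10 mg daily", "20 mg daily"),
    c("2021-06-05", "2021-07-20"), c("2021-07-20", NA))
  ann <- bp_annotations(c("2021-07-10", "2021-07-10", "2021-10-01"),
                        c("Started diet", "Bought new cuff", "outside window"))
  model <- build_display_model(ms, meds, ann, demo_config())

  expect_equal(nrow(model$table), nrow(model$bins))
  expect_equal(sum(model$table$gap), nrow(model$bins) - nrow(model$points))
  # same-date annotations stack into one marker with concatenated text
  expect_equal(nrow(model$annotations), 1L)
  expect_equal(model$annotations$n_notes, 2L)
  expect_match(model$annotations$text, "Started diet; Bought new cuff")
  # dose change: one lane, two adjacent courses, first clipped to window
  expect_equal(unique(model$medications$lane), 1L)
  expect_equal(nrow(model$medications), 2L)
  expect_equal(model$medications$start[1], as.Date("2021-07-01"))
  expect_true(model$medications$ongoing[2])
  # goal bands always inside the y-domain
  expect_lte(model$ylim[1], model$bands$diastolic[1])
  expect_gte(model$ylim[2], model$bands$systolic[2])
})

test_that("like-with-like: in-band position and in_range status coincide", {
  s <- simulate_bp_series(sim_params(seed = 17, cadence_minutes = 1440),
                          c("2021-07-01", "2021-09-01"))
  model <- build_display_model(s, config = demo_config())
  g <- model$config$goal
  in_band_s <- model$points$mean_systolic >= g$sbp_low &
    model$points$mean_systolic <= g$sbp_high
  in_band_d <- model$points$mean_diastolic >= g$dbp_low &
    model$points$mean_diastolic <= g$dbp_high
  expect_equal(in_band_s, model$goal_status$systolic_status == "in_range")
  expect_equal(in_band_d, model$goal_status$diastolic_status == "in_range")
  # every out-of-range point gets a bold table cell
  tab <- model$table[match(model$points$bin_index, model$table$bin_index), ]
  expect_true(all(tab$bold_systolic[!in_band_s]))
  expect_true(all(tab$bold_diastolic[!in_band_d]))
})

test_that("clipping a medication course never changes its lane", {
  meds <- medication_courses(
    c("Amlodipine", "Lisinopril", "Chlorthalidone"),
    c("5 mg", "10 mg", "25 mg"),
    c("2021-01-10", "2021-06-15", "2021-07-10"),
    c(NA, NA, NA))
  ms <- demo_measurements()
  wide <- build_display_model(ms, meds, config = display_config(
    window = c("2021-01-01", "2021-12-01")))
  narrow <- build_display_model(ms, meds, config = demo_config())
  lane_of <- function(m, name) unique(m$medications$lane[m$medications$name == name])
  for (nm in meds$name) {
    expect_equal(lane_of(narrow, nm), lane_of(wide, nm), info = nm)
  }
  # the clipped course is truncated to the window, lane intact
  expect_equal(narrow$medications$start[narrow$medications$name == "Amlodipine"],
               as.Date("2021-07-01"))
})

test_that("empty inputs give a valid empty-plot model", {
  model <- build_display_model(
    bp_measurements(character(), numeric(), numeric()),
    config = demo_config())
  expect_s3_class(model, "bp_display_model")
  expect_equal(nrow(model$points), 0L)
  expect_equal(nrow(model$segments), 0L)
  expect_null(model$smooth)
  expect_true(all(model$table$gap))
  expect_equal(nrow(model$annotations), 0L)
  expect_equal(nrow(model$medications), 0L)
  # bands still define the y-domain
  expect_equal(model$ylim, c(60 - 5, 140 + 5))
})
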
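# bpdisplay

**bpdisplay** is an R engine for the kind of blood pressure display a
hypertensive patient and their clinician can read together during a visit.
Home BP measurements predict cardiovascular outcomes at least as well as
office readings, and connected cuffs are about to flood records with them —
but stock EHR charts plot raw values on autoscaled axes, with no goal
context, and fall over when one day holds a hundred readings. This package
turns measurement streams (CSV or FHIR R4 Observation bundles), medication
courses and dated free-text notes into a linked multi-panel display — line
graph, value table, annotation timeline, medication lanes — rendered as
deterministic static SVG or a self-contained interactive HTML file with a
cross-panel scrubber. It is aimed at clinical-informatics developers
embedding a BP view in a portal or SMART-on-FHIR app, and at researchers
studying BP data presentation.

## What the engine computes

* **Density schedule.** A display window of length *T* maps to a bin width
  *w* and a point cap: 1 day → 30-min bins (48 points), 1 week → 3 h (56),
  2 weeks → 6 h (56), 1 month → 12 h (62), 2 months → 1 day (62),
  4 months → 2 days (62), 6 months → 3 days (62), 1 year → 1 week (54),
  2 years → 2 weeks (54), then month-denominated widths capped at 60, so
  **no window ever shows more than 62 points**. Unlisted lengths snap up to
  the next listed period. Each non-empty half-open bin displays the
  arithmetic mean of its members, with circles for home-majority bins and
  squares otherwise; multi-measurement bins are flagged bold in the table.
* **Missing data.** For a maximal run of *L* empty bins in an *n*-bin
  window, the bridging line segment is drawn dashed iff *L/n* > 0.10
  (threshold configurable); smaller gaps connect solid, and the table keeps
  gap rows either way.
* **Robust trend.** LOWESS per channel: at each abscissa x_i, a degree-1
  weighted least squares over the ⌈f·n⌉ nearest neighbours with tricube
  weights w = (1 − (d/d_max)³)³, followed by bisquare robustness passes
  (weights (1 − (r/6m)²)² with m the median absolute residual). Defaults
  f = 0.30, 2 robustness passes. The raw polyline is faded (opacity 0.45)
  under the full-opacity smooth.
* **Goal classification.** Inclusive per-channel comparison against a goal
  range (default 90–140 mmHg systolic, 60–90 diastolic), drawn as filled
  bands in the channel's own hue — mint `#008471` for systolic, cocoa
  `#9C652B` for diastolic — so "dot inside same-coloured band" reads as
  in-range at a glance (the like-with-like paradigm). Out-of-range values
  are bold in the table; the y-axis always contains both bands.
* **Synthetic streams.** A seeded generator (circadian sinusoid + AR(1)
  level + cuff noise + white-coat office offset + outliers + sigmoidal
  medication response + missing runs) exercises every stage without any
  patient data.

## Worked example

```r
library(bpdisplay)

scn   <- simulate_scenario("nascence", seed = 42)   # weekly home readings, 6 months
cfg   <- display_config(window = scn$window)
model <- build_display_model(scn$measurements, scn$medications,
                             scn$annotations, cfg)
model
#> BP display model: 2021-01-01 to 2021-07-01 ('6 months' schedule, 61 bins, 30 points, 31 gap rows)
#>   annotations: 2; medication courses: 2 in 1 lane(s)

head(subset(model$table, !gap), 4)
#>   bin_index      label systolic diastolic bold_systolic bold_diastolic   gap
#> 1         1 2021-01-01      132        91         FALSE           TRUE FALSE
#> 3         3 2021-01-07      130        75         FALSE          FALSE FALSE
#> 5         5 2021-01-13      130        82         FALSE          FALSE FALSE
#> 6         6 2021-01-16      148        96          TRUE           TRUE FALSE
```

The six-month window selects 3-day bins (61 bins here, under the 62-point
cap); 30 bins hold a reading and 31 render as gap rows. Row 1's diastolic
91 mmHg exceeds the 60–90 goal band, so that cell is bold; row 6 is out of
range on both channels. The lisinopril dose change (10 mg → 20 mg) occupies
one medication lane as two adjacent courses.

```r
writeLines(render_svg(model), "display.svg")    # static, byte-deterministic
writeLines(render_html(model), "display.html")  # scrubber + hover annotations
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/bpdisplay.R simulate  --preset abundance --seed 1 --out-dir demo/
Rscript inst/cli/bpdisplay.R aggregate --in demo/measurements.csv \
    --start 2021-06-01 --end 2021-06-15 --out demo/points.csv
Rscript inst/cli/bpdisplay.R render    --in demo/measurements.csv \
    --start 2021-06-01 --end 2021-06-15 --format html --out demo/display.html
```

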
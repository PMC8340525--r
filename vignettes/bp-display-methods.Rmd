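---
title: "Methods behind the bpdisplay engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the bpdisplay engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpdisplay)
```

## The problem

A blood pressure record mixes sparse office readings, increasingly dense
home-cuff uploads, and (soon) near-continuous wearable streams. A display
that a patient and clinician read together has to (i) stay legible at any
density, (ii) make in-range vs out-of-range status pre-attentively visible,
(iii) de-emphasise the outliers and variability that patients over-weight
relative to the clinically meaningful mean trend, and (iv) keep
medications, notes and values on one shared time axis. bpdisplay resolves
raw inputs into a renderer-independent *display model* and renders that
model deterministically; everything quantitative happens before rendering,
so it can be tested without pixels.

## Density schedule and aggregation

The engine never plots more than 62 points. A requested window snaps **up**
to the smallest listed schedule period that covers it; each row fixes a bin
width and a cap (48–62). Bins are half-open intervals anchored at the
window start, not at calendar boundaries: calendar-aligned bins can exceed
a row's cap by one (a 2-month window straddling month edges touches 63
calendar days), while window-anchored fixed-width bins provably cannot.
For the month-denominated rows the bin width is fixed at the calendar
maximum of the nominal span — 31, 62, 123, 184 and 366 days for 1, 2, 4, 6
and 12 months — which guarantees the cap for every window that snaps to
the row. The caps themselves are calendar facts, which the package
recomputes by enumeration (`max_consecutive_month_days()`,
`calendar_week_count()`): any two consecutive months hold at most 62 days
(July + August), four at most 123, six at most 184, and a calendar year
touches at most 54 distinct Monday-anchored weeks. Week bins are 7-day
intervals from the window start; they cannot simultaneously align with
calendar weeks and the window, and we prefer the cap guarantee to calendar
alignment. Supported windows run to 60 years (one-year bins, cap 60);
beyond that the schedule's final row cannot respect its own cap and
`make_bins()` refuses rather than overflow the display.

Each non-empty bin displays the **arithmetic mean** of its members
(medians were considered; the schedule's own wording is an average, and
outlier resistance is the smoothing layer's job). The count travels with
the point: the graph shows no aggregation cue, the data table sets
multi-measurement values in bold. Symbols stay binary — circles for
home-majority bins, squares otherwise — with ties going to the square,
since office values are staff-validated. 24-h ambulatory readings are
accepted and mapped to the home symbol (they are self-context
measurements); the mapping is a single function (`source_symbol()`) if a
deployment disagrees.

## Missing data

For each maximal run of `L` empty bins among `n`, the single bridging
segment is dashed iff `L / n > 0.10`. Two readings are deliberate:

* the fraction is taken **relative to the whole window's bin count**, not
  to a local neighbourhood — the closest reading of "10% of consecutive
  data points", and the one that makes styles a pure function of the
  empty-bin mask (a property the tests assert);
* the comparison is **strict**: exactly 10% renders solid. The boundary is
  undefined in prose ("< 10%" solid, "> 10%" dashed); solid is the less
  alarming default and the choice is configurable via
  `missing_threshold`.

Leading and trailing empty bins have nothing to bridge and produce no
segment; a window with zero non-empty bins raises a typed `bp_no_points`
condition that `build_display_model()` converts into a valid empty-plot
model. Filling an empty bin can only split a run, so it can never turn a
solid bridge dashed (tested by simulation).

## LOWESS smoothing

The trend layer is Cleveland-style LOWESS, implemented in the package: at
each abscissa the fit is a degree-1 weighted least squares over the
`ceiling(frac * n)` nearest neighbours, tricube-weighted by distance, then
`robust_iterations` bisquare re-weighting passes using six median absolute
residuals as the cut. Defaults `frac = 0.30`, `robust_iterations = 2`:
30% neighbourhoods resolve multi-week trend at the schedule's 48–62-point
densities, and two robustness passes give outliers near-zero weight, which
is the display's reason for smoothing at all. Numerical details: the
abscissa is time in **days since the window start** (neighbourhoods must be
time-based when bins are missing — gaps simply widen the local window);
ties in neighbour distance break by index; a numerically degenerate
neighbourhood falls back to the weighted mean; fewer than two distinct
abscissae disable smoothing with a warning and the raw line renders at
full opacity. Smoothing operates on the aggregated bin means, one curve
per channel with home and office pooled, so curve and polyline share
abscissae. Correctness is checked against an independently written
per-point `lm.wfit` oracle (max |Δ| < 1e-6 on 200-point noisy series) and
against exact cases: constants and lines reproduce exactly, and the fit is
shift- and scale-equivariant including the robustness passes.

## Goal classification and the like-with-like display

Each channel classifies independently against its goal range with
**inclusive** bounds (140/90 on the default range is in range; the
convention is configurable by overriding the range). Defaults are
90–140 mmHg systolic and 60–90 diastolic, personalisable per patient. The
bands are drawn behind the data in the channel hues — mint `#008471`
systolic, cocoa `#9C652B` diastolic, a colourblind-safe pair — at fill
opacity 0.18, and the y-domain is forced to contain both bands plus a
5 mmHg pad, so autoscaling can never crop the clinical context. No other
out-of-range affordance exists (no enlarged or recoloured markers, no
fills): position against the band plus a bold table cell is the entire
encoding. Band opacity 0.18 and raw-line opacity 0.45 are theme
parameters; "pastel" and "faded" have no canonical numbers, these keep the
smooth line dominant.

## Annotations, medications, serialization

Annotations are date + text only. Markers sit on the shared x-axis;
same-date annotations stack into one marker with concatenated text to
avoid clutter. Interactive output reveals the text on hover (hidden by
default); static SVG, where hover does not exist, emits a numbered
footnote list instead so printing loses nothing. Medication courses get
one lane per drug name, lanes ordered by each name's first start date over
the *full* course list, so clipping courses to the window never reassigns
lanes; a dose change is two adjacent intervals in one lane. The resolved
model serializes to JSON (`write_display_json()` /
`read_display_json()`) with fixed key order and full numeric precision;
the round trip is byte-stable and asserted in tests.

## Rendering

Both renderers are deterministic string templating over the model: no
timestamps, coordinates fixed at three decimals, so identical models give
byte-identical output — snapshot-friendly and diffable. Every panel group
carries the shared x-scale as `data-x0/x1/t0/t1` attributes; the tests
decode these per panel and check that any pixel maps to the same date
everywhere, which is exactly the property the HTML scrubber relies on. The
HTML file is self-contained (inline style and a small script, no network
references, no charting framework), so it works from disk and remains
archival.

## The synthetic generator

`simulate_bp_series()` is a test-bed process, not physiology:

| parameter | default | role |
|---|---|---|
| baseline SBP/DBP | 135 / 84 mmHg | uncontrolled-hypertensive resting level |
| circadian amplitude | 8 mmHg | within-day sinusoid (peak mid-afternoon) |
| AR(1) rho / sd | 0.6 / `noise_sd` | slowly wandering true level |
| measurement noise | 7 mmHg | per-reading cuff error |
| office offset | +10 mmHg | white-coat effect on office readings |
| outliers | rate 0.02, ±30 mmHg | stress spikes, technique errors |
| cadence | 720 min | twice-daily home readings |
| office interval | 30 days | clinic visits (10:00, pinned to the day) |

Diastolic values couple to the systolic deviation with slope 0.62 plus
independent noise, clipped to keep SBP > DBP — enough to keep every
generated row valid without a hemodynamic model. Medication effects are
sigmoidal drops (unit-day scale) beginning at start + onset delay. All
randomness derives from one seed split into fixed sub-streams, so adding a
generator feature does not shift existing draws. What the generator does
**not** emulate: seasonal drift, measurement rounding to even digits,
device-specific bias, adherence lapses, or correlated missingness —
passing tests demonstrate the pipeline's arithmetic and contracts on
realistic-shaped data, not performance on real patients.
`simulate_paired_readings()` emits home/office pairs sharing one latent
value (a cuff-validation visit), which is what makes the configured office
offset identifiable to within `noise_sd * sqrt(2/n)`.

## Problem sizes and verification

The test suite builds everything in code at run time: schedule checks
enumerate all rows; property tests use 62-bin two-month windows and 100-bin
grids for the exact-threshold case; LOWESS equivalence uses 200-point
seeded series; conservation checks run a handful of seeded streams;
parameter recovery uses 500–1000 pairs and a four-year twice-daily series
(the autocorrelated level needs that length for the pre/post means to pin
a 15 mmHg drop within ±2 mmHg). The whole suite runs in seconds.

## Known limitations

* Timestamps are timezone-naive local clinic time; no DST arithmetic.
* Windows beyond 60 years are refused rather than re-binned.
* The FHIR reader targets R4 Observation shapes read-only; there is no
  SMART launch handshake, and the `confirmed` flag has no standard FHIR
  home — we read a documented extension and default to unconfirmed.
* The data table renders one column per bin; below ~12 px per column the
  font floor (5 px) makes print magnification necessary.
* Dose strings are labels, not parsed quantities; lanes encode identity
  and duration, not dose intensity.
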
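#' Rendering theme
#'
#' Visual constants of the display. The defaults implement the final
#' two-color like-with-like scheme: mint `#008471` for everything systolic
#' (points, line, smooth curve, goal band) and cocoa `#9C652B` for
#' everything diastolic; goal bands are the channel hue at a pastel fill
#' opacity; the raw polyline is faded (opacity 0.45) so the heavier,
#' fully-opaque smoothing line stands out; circles mark home readings and
#' squares office readings; dashed strokes bridge large missing runs.
#'
#' @param systolic_color,diastolic_color 6-digit hex channel hues.
#' @param band_alpha goal-band fill opacity in (0, 1].
#' @param raw_opacity raw polyline opacity; must be < `smooth_opacity`.
#' @param smooth_opacity smoothing-line opacity.
#' @param raw_width,smooth_width stroke widths in px; the smooth line is
#'   heavier.
#' @param dash_pattern SVG `stroke-dasharray` for missing-run bridges.
#' @param marker_radius point marker radius in px.
#' @return A `bp_render_theme` object.
#' @export
render_theme <- function(systolic_color = "#008471",
                         diastolic_color = "#9C652B",
                         band_alpha = 0.18,
                         raw_opacity = 0.45,
                         smooth_opacity = 1.0,
                         raw_width = 1.2,
                         smooth_width = 2.5,
                         dash_pattern = "6,4",
                         marker_radius = 3.2) {
  if (!is_hex_color(systolic_color) || !is_hex_color(diastolic_color)) {
    stop("theme colors must be 6-digit hex strings", call. = FALSE)
  }
  stopifnot(band_alpha > 0, band_alpha <= 1,
            raw_opacity > 0, smooth_opacity <= 1,
            raw_opacity < smooth_opacity,
            raw_width > 0, smooth_width > 0, marker_radius > 0)
  structure(list(systolic_color = systolic_color,
                 diastolic_color = diastolic_color,
                 band_alpha = band_alpha,
                 raw_opacity = raw_opacity,
                 smooth_opacity = smooth_opacity,
                 raw_width = raw_width,
                 smooth_width = smooth_width,
                 dash_pattern = dash_pattern,
                 marker_radius = marker_radius),
            class = "bp_render_theme")
}

theme_from_config <- function(config) {
  render_theme(systolic_color = config$systolic_color,
               diastolic_color = config$diastolic_color,
               band_alpha = config$band_alpha)
}
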
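# Fixed 3-decimal coordinate formatting: identical models render to
# identical bytes (no timestamps, no environment-dependent output).
fmt3 <- function(x) formatC(x, format = "f", digits = 3)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Shared geometry for all panels. One x-scale serves every panel; each
# panel group carries the scale as data attributes so any consumer (the
# scrubber, tests) can decode pixel -> date identically everywhere.
svg_layout <- function(model, width = 960) {
  n_lanes <- if (nrow(model$medications)) max(model$medications$lane) else 0L
  n_ann <- nrow(model$annotations)
  ml <- 56; mr <- 16; mt <- 14
  plot_h <- 280; axis_h <- 20; ann_h <- 22
  med_h <- 10 + 20 * max(n_lanes, 0L) + 8
  table_h <- 60
  foot_h <- if (n_ann > 0) 12 + 14 * n_ann else 0
  list(width = width, ml = ml, mr = mr, mt = mt,
       x0 = ml, x1 = width - mr,
       plot_top = mt, plot_bot = mt + plot_h,
       axis_top = mt + plot_h,
       ann_top = mt + plot_h + axis_h,
       med_top = mt + plot_h + axis_h + ann_h,
       table_top = mt + plot_h + axis_h + ann_h + med_h,
       foot_top = mt + plot_h + axis_h + ann_h + med_h + table_h,
       height = mt + plot_h + axis_h + ann_h + med_h + table_h + foot_h + 10,
       n_lanes = n_lanes, n_ann = n_ann)
}

scale_attrs <- function(model, L) {
  sprintf('data-x0="%s" data-x1="%s" data-t0="%s" data-t1="%s"',
          fmt3(L$x0), fmt3(L$x1),
          fmt_time(model$window[1]), fmt_time(model$window[2]))
}

make_xscale <- function(model, L) {
  t0 <- as.numeric(model$window[1])
  t1 <- as.numeric(model$window[2])
  function(t) L$x0 + (as.numeric(t) - t0) / (t1 - t0) * (L$x1 - L$x0)
}

make_yscale <- function(model, L) {
  lo <- model$ylim[1]
  hi <- model$ylim[2]
  function(v) L$plot_top + (hi - v) / (hi - lo) * (L$plot_bot - L$plot_top)
}

channel_geom <- function(model, channel) {
  pts <- model$points
  if (channel == "systolic") {
    list(v = pts$mean_systolic, band = model$bands$systolic)
  } else {
    list(v = pts$mean_diastolic, band = model$bands$diastolic)
  }
}

svg_plot_panel <- function(model, theme, L, xs, ys) {
  out <- c(sprintf('<g class="panel panel-plot" %s>', scale_attrs(model, L)))
  out <- c(out, sprintf(
    '<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#CCCCCC" stroke-width="1"/>',
    fmt3(L$x0), fmt3(L$plot_top), fmt3(L$x1 - L$x0),
    fmt3(L$plot_bot - L$plot_top)))
  # goal bands behind everything, each in its channel's hue (like-with-like)
  for (ch in c("systolic", "diastolic")) {
    g <- channel_geom(model, ch)
    col <- if (ch == "systolic") theme$systolic_color else theme$diastolic_color
    out <- c(out, sprintf(
      '<rect class="band band-%s" x="%s" y="%s" width="%s" height="%s" fill="%s" fill-opacity="%s"/>',
      ch, fmt3(L$x0), fmt3(ys(g$band[2])), fmt3(L$x1 - L$x0),
      fmt3(ys(g$band[1]) - ys(g$band[2])), col, fmt3(theme$band_alpha)))
  }
  # y axis ticks
  for (v in pretty(model$ylim, n = 6)) {
    if (v < model$ylim[1] || v > model$ylim[2]) next
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#DDDDDD" stroke-width="0.5"/>',
      fmt3(L$x0), fmt3(ys(v)), fmt3(L$x1), fmt3(ys(v))),
      sprintf('<text x="%s" y="%s" font-size="9" text-anchor="end" fill="#444444">%g</text>',
              fmt3(L$x0 - 4), fmt3(ys(v) + 3), v))
  }
  out <- c(out, sprintf(
    '<text x="%s" y="%s" font-size="9" fill="#444444" transform="rotate(-90 %s %s)" text-anchor="middle">mmHg</text>',
    fmt3(14), fmt3((L$plot_top + L$plot_bot) / 2),
    fmt3(14), fmt3((L$plot_top + L$plot_bot) / 2)))
  pts <- model$points
  if (nrow(pts) > 0L) {
    mid <- (as.numeric(pts$start) + as.numeric(pts$end)) / 2
    px <- xs(mid)
    by_bin <- stats::setNames(seq_len(nrow(pts)), pts$bin_index)
    raw_op <- if (is.null(model$smooth)) 1.0 else theme$raw_opacity
    for (ch in c("systolic", "diastolic")) {
      g <- channel_geom(model, ch)
      col <- if (ch == "systolic") theme$systolic_color else theme$diastolic_color
      py <- ys(g$v)
      # per-segment polyline: solid between neighbours, dashed over big gaps
      if (nrow(model$segments) > 0L) {
        for (k in seq_len(nrow(model$segments))) {
          i <- by_bin[[as.character(model$segments$from_bin[k])]]
          j <- by_bin[[as.character(model$segments$to_bin[k])]]
          dash <- if (model$segments$style[k] == "dashed") {
            sprintf(' stroke-dasharray="%s"', theme$dash_pattern)
          } else {
            ""
          }
          out <- c(out, sprintf(
            '<line class="raw raw-%s seg-%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s" stroke-opacity="%s"%s/>',
            ch, model$segments$style[k], fmt3(px[i]), fmt3(py[i]),
            fmt3(px[j]), fmt3(py[j]), col, fmt3(theme$raw_width),
            fmt3(raw_op), dash))
        }
      }
      # markers: circles for home, squares for office-like sources
      for (i in seq_len(nrow(pts))) {
        if (pts$source_symbol[i] == "circle_home") {
          out <- c(out, sprintf(
            '<circle class="pt pt-%s" cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="%s"/>',
            ch, fmt3(px[i]), fmt3(py[i]), fmt3(theme$marker_radius), col,
            fmt3(raw_op)))
        } else {
          s <- theme$marker_radius
          out <- c(out, sprintf(
            '<rect class="pt pt-%s" x="%s" y="%s" width="%s" height="%s" fill="%s" fill-opacity="%s"/>',
            ch, fmt3(px[i] - s), fmt3(py[i] - s), fmt3(2 * s), fmt3(2 * s),
            col, fmt3(raw_op)))
        }
      }
    }
  }
  # smoothing line: heavier and fully opaque so the trend dominates
  if (!is.null(model$smooth) && nrow(model$smooth) >= 2L) {
    sm <- model$smooth
    t0 <- as.numeric(model$window[1])
    smx <- xs(t0 + sm$x_days * DAY)
    for (ch in c("systolic", "diastolic")) {
      col <- if (ch == "systolic") theme$systolic_color else theme$diastolic_color
      vals <- if (ch == "systolic") sm$systolic else sm$diastolic
      pts_txt <- paste(fmt3(smx), fmt3(ys(vals)), sep = ",", collapse = " ")
      out <- c(out, sprintf(
        '<polyline class="smooth smooth-%s" points="%s" fill="none" stroke="%s" stroke-width="%s" stroke-opacity="%s"/>',
        ch, pts_txt, col, fmt3(theme$smooth_width), fmt3(theme$smooth_opacity)))
    }
  }
  c(out, "</g>")
}

svg_axis_panel <- function(model, L, xs) {
  t0 <- as.numeric(model$window[1])
  t1 <- as.numeric(model$window[2])
  sub_day <- (t1 - t0) <= DAY * 1.5
  ticks <- t0 + (0:5) / 5 * (t1 - t0)
  lab <- format(as.POSIXct(ticks, origin = "1970-01-01", tz = "UTC"),
                if (sub_day) "%H:%M" else "%Y-%m-%d")
  out <- c(sprintf('<g class="panel panel-axis" %s>', scale_attrs(model, L)))
  for (i in seq_along(ticks)) {
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#888888" stroke-width="1"/>',
      fmt3(xs(ticks[i])), fmt3(L$axis_top), fmt3(xs(ticks[i])),
      fmt3(L$axis_top + 4)),
      sprintf('<text x="%s" y="%s" font-size="9" text-anchor="middle" fill="#444444">%s</text>',
              fmt3(xs(ticks[i])), fmt3(L$axis_top + 15), lab[i]))
  }
  c(out, "</g>")
}

svg_annotation_panel <- function(model, L, xs, interactive = FALSE) {
  out <- c(sprintf('<g class="panel panel-annotations" %s>',
                   scale_attrs(model, L)))
  y <- L$ann_top + 10
  out <- c(out, sprintf(
    '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#BBBBBB" stroke-width="0.5"/>',
    fmt3(L$x0), fmt3(y), fmt3(L$x1), fmt3(y)))
  ann <- model$annotations
  tips <- character()
  for (i in seq_len(nrow(ann))) {
    ax <- xs(as.POSIXct(paste(format(ann$date[i]), "12:00:00"), tz = "UTC"))
    out <- c(out, sprintf(
      '<path class="ann-marker" data-tip="tip-%d" d="M %s %s L %s %s L %s %s L %s %s Z" fill="#555555"/>',
      ann$index[i], fmt3(ax), fmt3(y - 5), fmt3(ax + 4), fmt3(y),
      fmt3(ax), fmt3(y + 5), fmt3(ax - 4), fmt3(y)),
      sprintf('<text x="%s" y="%s" font-size="7" text-anchor="middle" fill="#555555">%d</text>',
              fmt3(ax), fmt3(y + 14), ann$index[i]))
    if (interactive) {
      tx <- min(max(ax, L$x0 + 80), L$x1 - 80)
      tips <- c(tips, sprintf(
        '<g class="ann-tip" id="tip-%d" visibility="hidden"><rect x="%s" y="%s" width="160" height="26" rx="4" fill="#FFFFF0" stroke="#999999"/><text x="%s" y="%s" font-size="8" text-anchor="middle" fill="#222222">%s: %s</text></g>',
        ann$index[i], fmt3(tx - 80), fmt3(y - 38), fmt3(tx), fmt3(y - 22),
        format(ann$date[i]), xml_escape(ann$text[i])))
    }
  }
  c(out, tips, "</g>")
}

svg_medication_panel <- function(model, L, xs) {
  out <- c(sprintf('<g class="panel panel-medications" %s>',
                   scale_attrs(model, L)))
  out <- c(out, sprintf(
    '<text x="%s" y="%s" font-size="9" fill="#444444">Medications</text>',
    fmt3(4), fmt3(L$med_top + 10)))
  meds <- model$medications
  for (i in seq_len(nrow(meds))) {
    y <- L$med_top + 6 + (meds$lane[i] - 1L) * 20
    bx0 <- xs(as.POSIXct(paste(format(meds$start[i]), "00:00:00"), tz = "UTC"))
    bx1 <- xs(as.POSIXct(paste(format(meds$end[i]), "00:00:00"), tz = "UTC"))
    bx1 <- min(bx1, L$x1)
    bx0 <- max(bx0, L$x0)
    out <- c(out, sprintf(
      '<rect class="med-course" x="%s" y="%s" width="%s" height="14" fill="#E4E4E4" stroke="#888888" stroke-width="0.8"/>',
      fmt3(bx0), fmt3(y), fmt3(max(bx1 - bx0, 1))),
      sprintf('<text class="med-label" x="%s" y="%s" font-size="8" fill="#222222">%s %s</text>',
              fmt3(bx0 + 3), fmt3(y + 10),
              xml_escape(meds$name[i]), xml_escape(meds$dose[i])))
  }
  c(out, "</g>")
}

svg_table_panel <- function(model, L, xs) {
  out <- c(sprintf('<g class="panel panel-table" %s>', scale_attrs(model, L)))
  tab <- model$table
  n <- nrow(tab)
  col_w <- (L$x1 - L$x0) / max(n, 1L)
  fs <- max(5, min(11, floor(col_w * 0.48)))
  y_sbp <- L$table_top + 22
  y_dbp <- L$table_top + 40
  out <- c(out,
    sprintf('<text x="%s" y="%s" font-size="9" fill="%s">SBP</text>',
            fmt3(4), fmt3(y_sbp), model$config$systolic_color),
    sprintf('<text x="%s" y="%s" font-size="9" fill="%s">DBP</text>',
            fmt3(4), fmt3(y_dbp), model$config$diastolic_color),
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#CCCCCC" stroke-width="0.5"/>',
            fmt3(L$x0), fmt3(L$table_top + 6), fmt3(L$x1), fmt3(L$table_top + 6)))
  for (i in seq_len(n)) {
    cx <- L$x0 + (i - 0.5) * col_w
    bold_s <- if (tab$bold_systolic[i]) ' font-weight="bold"' else ""
    bold_d <- if (tab$bold_diastolic[i]) ' font-weight="bold"' else ""
    cls <- if (tab$gap[i]) "cell gap" else "cell"
    out <- c(out, sprintf(
      '<text class="%s" x="%s" y="%s" font-size="%d" text-anchor="middle" fill="#222222"%s>%s</text>',
      cls, fmt3(cx), fmt3(y_sbp), fs, bold_s, xml_escape(tab$systolic[i])),
      sprintf(
      '<text class="%s" x="%s" y="%s" font-size="%d" text-anchor="middle" fill="#222222"%s>%s</text>',
      cls, fmt3(cx), fmt3(y_dbp), fs, bold_d, xml_escape(tab$diastolic[i])))
  }
  c(out, "</g>")
}

svg_footnotes <- function(model, L) {
  ann <- model$annotations
  if (nrow(ann) == 0L) return(character())
  out <- c('<g class="panel panel-footnotes">')
  for (i in seq_len(nrow(ann))) {
    out <- c(out, sprintf(
      '<text class="footnote" x="%s" y="%s" font-size="9" fill="#333333">[%d] %s: %s</text>',
      fmt3(L$ml), fmt3(L$foot_top + 10 + 14 * (i - 1)), ann$index[i],
      format(ann$date[i]), xml_escape(ann$text[i])))
  }
  c(out, "</g>")
}

build_svg <- function(model, theme, width = 960, interactive = FALSE) {
  stopifnot(inherits(model, "bp_display_model"),
            inherits(theme, "bp_render_theme"))
  L <- svg_layout(model, width)
  xs <- make_xscale(model, L)
  ys <- make_yscale(model, L)
  body <- c(
    svg_plot_panel(model, theme, L, xs, ys),
    svg_axis_panel(model, L, xs),
    svg_annotation_panel(model, L, xs, interactive = interactive),
    svg_medication_panel(model, L, xs),
    svg_table_panel(model, L, xs),
    if (!interactive) svg_footnotes(model, L),
    if (interactive) sprintf(
      '<line id="scrubber" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#E0B000" stroke-width="1.5" visibility="hidden"/>',
      fmt3(L$x0), fmt3(L$plot_top), fmt3(L$x0), fmt3(L$table_top + 46)))
  height <- if (interactive) L$foot_top + 6 else L$height
  paste(c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" id="bp-svg" width="%d" height="%s" viewBox="0 0 %d %s" font-family="sans-serif">',
    width, fmt3(height), width, fmt3(height)),
    body, "</svg>"), collapse = "\n")
}

#' Render a display model to static SVG
#'
#' All panels (plot with goal bands, per-segment styled polylines, smooth
#' curves and shaped markers; x-axis; annotation timeline; medication lanes;
#' data table with bold out-of-range/aggregate cells) are stacked over one
#' shared x-scale, declared on every panel group as
#' `data-x0`/`data-x1`/`data-t0`/`data-t1` attributes. Because hover text
#' is unavailable in print, annotations additionally render as a numbered
#' footnote list. Output is deterministic: the same model renders to
#' byte-identical SVG (no timestamps; fixed 3-decimal coordinates).
#'
#' @param model a `bp_display_model`.
#' @param theme a [render_theme()]; defaults to the model config's hues.
#' @param width output width in px.
#' @return SVG document as a single string.
#' @export
render_svg <- function(model, theme = NULL, width = 960) {
  if (is.null(theme)) theme <- theme_from_config(model$config)
  build_svg(model, theme, width, interactive = FALSE)
}
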
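#' Render a display model to self-contained interactive HTML
#'
#' A single file with inline style and script and no network references:
#' it works opened from disk with no connection. Interactivity is minimal
#' scripting over the static SVG — no charting framework — so the output
#' stays archival:
#' * a vertical scrubber line spanning plot, annotation track, medication
#'   lanes and data table follows the cursor; because every panel declares
#'   the same x-scale metadata, the scrubber marks the same date in all of
#'   them;
#' * annotation bubbles are hidden by default and revealed only while the
#'   cursor hovers their x-axis marker.
#'
#' @inheritParams render_svg
#' @return HTML document as a single string.
#' @export
render_html <- function(model, theme = NULL, width = 960) {
  if (is.null(theme)) theme <- theme_from_config(model$config)
  svg <- build_svg(model, theme, width, interactive = TRUE)
  script <- paste(
    "(function () {",
    "  var svg = document.getElementById('bp-svg');",
    "  var sc = document.getElementById('scrubber');",
    "  var panel = svg.querySelector('.panel');",
    "  var x0 = parseFloat(panel.getAttribute('data-x0'));",
    "  var x1 = parseFloat(panel.getAttribute('data-x1'));",
    "  svg.addEventListener('mousemove', function (e) {",
    "    var pt = svg.createSVGPoint();",
    "    pt.x = e.clientX; pt.y = e.clientY;",
    "    var p = pt.matrixTransform(svg.getScreenCTM().inverse());",
    "    var x = Math.max(x0, Math.min(x1, p.x));",
    "    sc.setAttribute('x1', x); sc.setAttribute('x2', x);",
    "    sc.setAttribute('visibility', 'visible');",
    "  });",
    "  svg.addEventListener('mouseleave', function () {",
    "    sc.setAttribute('visibility', 'hidden');",
    "  });",
    "  var markers = svg.querySelectorAll('.ann-marker');",
    "  markers.forEach(function (m) {",
    "    var tip = document.getElementById(m.getAttribute('data-tip'));",
    "    if (!tip) { return; }",
    "    m.addEventListener('mouseenter', function () {",
    "      tip.setAttribute('visibility', 'visible');",
    "    });",
    "    m.addEventListener('mouseleave', function () {",
    "      tip.setAttribute('visibility', 'hidden');",
    "    });",
    "  });",
    "})();", sep = "\n")
  paste(c(
    "<!DOCTYPE html>",
    '<html lang="en">',
    "<head>",
    '<meta charset="utf-8"/>',
    "<title>Blood pressure display</title>",
    "<style>",
    "body { font-family: sans-serif; margin: 16px; background: #FFFFFF; }",
    ".ann-marker { cursor: pointer; }",
    "</style>",
    "</head>",
    "<body>",
    svg,
    "<script>",
    script,
    "</script>",
    "</body>",
    "</html>"), collapse = "\n")
}
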
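#' Tricube kernel weight
#'
#' The LOWESS neighbourhood kernel: `w = (1 - (d/dmax)^3)^3` for distances
#' inside the neighbourhood, 0 at and beyond its edge.
#'
#' @param d non-negative distance(s) from the fitting point.
#' @param dmax neighbourhood radius (> 0).
#' @return weights in \[0, 1\].
#' @examples
#' tricube_weight(0, 1)       # 1 at the centre
#' tricube_weight(0.5, 1)     # (1 - 0.125)^3
#' @export
tricube_weight <- function(d, dmax) {
  if (!is.numeric(dmax) || length(dmax) != 1L || dmax <= 0) {
    stop("dmax must be a positive scalar", call. = FALSE)
  }
  stopifnot(all(d >= 0))
  u <- pmin(d, dmax) / dmax
  (1 - u^3)^3
}

# Weighted degree-1 least squares evaluated at x0. Falls back to the
# weighted mean when the neighbourhood is numerically degenerate.
wls_at <- function(x, y, w, x0) {
  sw <- sum(w)
  if (sw <= 0) return(mean(y))
  xm <- sum(w * x) / sw
  ym <- sum(w * y) / sw
  dx <- x - xm
  den <- sum(w * dx * dx)
  if (den <= 1e-12 * max(1, max(abs(x))^2)) return(ym)
  b <- sum(w * dx * (y - ym)) / den
  ym + b * (x0 - xm)
}

#' Robust LOWESS smoothing of one series
#'
#' Cleveland-style locally weighted scatterplot smoothing: the fit at each
#' abscissa is a degree-1 weighted least squares over the `ceiling(frac * n)`
#' nearest neighbours with tricube weights, followed by `robust_iterations`
#' passes of bisquare residual re-weighting (residuals beyond six median
#' absolute residuals get zero weight). Neighbourhoods are defined by
#' distance along `x`, so gaps from missing bins simply widen the local
#' window rather than breaking the curve.
#'
#' @param x strictly increasing numeric abscissae (for the display: days
#'   since the window start).
#' @param y response values (mmHg).
#' @param frac neighbourhood fraction in (0, 1].
#' @param robust_iterations number of bisquare passes (>= 0).
#' @return fitted values at `x` (same length, same order).
#' @examples
#' x <- 1:20
#' lowess_fit(x, 2 * x + 1, frac = 0.5, robust_iterations = 0)
#' @export
lowess_fit <- function(x, y, frac = 0.30, robust_iterations = 2L) {
  n <- length(x)
  stopifnot(length(y) == n, frac > 0, frac <= 1, robust_iterations >= 0)
  if (n < 2L || length(unique(x)) < 2L) {
    stop("TooFewPoints: need at least 2 distinct x to smooth", call. = FALSE)
  }
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  q <- max(2L, min(n, as.integer(ceiling(frac * n))))
  rw <- rep(1, n)
  fit <- numeric(n)
  for (it in 0:robust_iterations) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      o <- order(d, seq_len(n))  # deterministic tie-break by index
      nb <- o[seq_len(q)]
      dmax <- d[nb[q]]
      w <- if (dmax > 0) tricube_weight(d[nb], dmax) else rep(1, q)
      w <- w * rw[nb]
      fit[i] <- wls_at(x[nb], y[nb], w, x[i])
    }
    if (it < robust_iterations) {
      r <- y - fit
      s <- stats::median(abs(r))
      if (s <= 0) {
        rw <- rep(1, n)
      } else {
        u <- pmin(abs(r) / (6 * s), 1)
        rw <- (1 - u^2)^2
      }
    }
  }
  fit
}

#' Smooth aggregated display points
#'
#' Applies [lowess_fit()] independently to the systolic and diastolic
#' channels of an aggregated series, at the bin midpoints, on a time axis of
#' days since the window start (so neighbourhood widths are time-based and
#' span missing bins). Home and office points are smoothed together as one
#' curve per channel, matching the connected two-line design.
#'
#' @param points a `bp_aggregated` frame from [aggregate_measurements()].
#' @param window_start window start datetime.
#' @param params a [smooth_params()].
#' @return data frame `bin_index`, `x_days`, `systolic`, `diastolic`, or
#'   `NULL` (with a warning) when smoothing is disabled or there are too few
#'   points — in that case the raw line renders at full opacity.
#' @export
smooth_points <- function(points, window_start, params = smooth_params()) {
  stopifnot(inherits(params, "bp_smooth_params"))
  if (!params$enabled) return(NULL)
  if (is.null(points) || nrow(points) < 2L) {
    warning("smoothing disabled: fewer than 2 aggregated points", call. = FALSE)
    return(NULL)
  }
  t0 <- as.numeric(as_bp_time(window_start))
  mid <- (as.numeric(points$start) + as.numeric(points$end)) / 2
  x <- (mid - t0) / DAY
  if (ceiling(params$frac * length(x)) < 2L && length(x) < 2L) {
    warning("smoothing disabled: neighbourhood too small", call. = FALSE)
    return(NULL)
  }
  data.frame(
    bin_index = points$bin_index,
    x_days = x,
    systolic = lowess_fit(x, points$mean_systolic, params$frac,
                          params$robust_iterations),
    diastolic = lowess_fit(x, points$mean_diastolic, params$frac,
                           params$robust_iterations))
}
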
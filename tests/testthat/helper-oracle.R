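# Independent LOWESS oracle: per-point weighted least squares via lm.wfit
# on an explicit design matrix, with tricube neighbourhood weights and
# bisquare robustness re-weighting. Shares no code with lowess_fit().
oracle_lowess <- function(x, y, frac, iters) {
  n <- length(x)
  q <- max(2L, min(n, as.integer(ceiling(frac * n))))
  rw <- rep(1, n)
  fit <- numeric(n)
  for (pass in 0:iters) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      nb <- order(d, seq_len(n))[seq_len(q)]
      dmax <- max(d[nb])
      w <- if (dmax > 0) (1 - pmin(d[nb] / dmax, 1)^3)^3 else rep(1, q)
      w <- w * rw[nb]
      fit[i] <- if (sum(w) <= 0) {
        mean(y[nb])
      } else {
        co <- stats::lm.wfit(cbind(1, x[nb]), y[nb], w)$coefficients
        if (anyNA(co)) {
          stats::weighted.mean(y[nb], w)
        } else {
          co[1] + co[2] * x[i]
        }
      }
    }
    if (pass < iters) {
      r <- y - fit
      s <- stats::median(abs(r))
      rw <- if (s <= 0) {
        rep(1, n)
      } else {
        u <- pmin(abs(r) / (6 * s), 1)
        (1 - u^2)^2
      }
    }
  }
  fit
}
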
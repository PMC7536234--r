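#' First-order (histogram) features of a normalized ROI
#'
#' Twenty statistics of the masked, 0-255-rescaled grey values. Moments use
#' population denominators; skewness and excess kurtosis fall back to 0 for
#' a constant ROI, as do the coefficient of variation and the quartile
#' coefficient of dispersion when their denominators vanish. Histogram
#' entropy and uniformity use `Ng` uniform bins over `[0, 256)`.
#'
#' @param roi a `normalized_roi`.
#' @param Ng histogram bin count for entropy/uniformity (default 32).
#' @return named numeric vector of length 20 (`F_stat.*`).
#' @export
first_order_features <- function(roi, Ng = 32L) {
  stopifnot(inherits(roi, "normalized_roi"))
  v <- roi$values[roi$mask]
  stopifnot(length(v) >= 16)
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  sdv <- sqrt(m2)
  skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - mu)^4) / m2^2 - 3 else 0
  q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  med <- q[3]
  core <- v[v >= q[1] & v <= q[5]] # 10-90 percentile trimmed set
  rmad <- if (length(core)) mean(abs(core - mean(core))) else 0
  counts <- tabulate(pmin(Ng, floor(v * Ng / 256) + 1L), nbins = Ng)
  p <- counts / n
  c(F_stat.mean = mu,
    F_stat.var = m2,
    F_stat.skew = skew,
    F_stat.kurt = kurt,
    F_stat.median = med,
    F_stat.min = min(v),
    F_stat.max = max(v),
    F_stat.range = max(v) - min(v),
    F_stat.p10 = q[1],
    F_stat.p90 = q[5],
    F_stat.iqr = q[4] - q[2],
    F_stat.mad = mean(abs(v - mu)),
    F_stat.rmad = rmad,
    F_stat.medad = mean(abs(v - med)),
    F_stat.cov = .sdiv(sdv, mu),
    F_stat.qcod = .sdiv(q[4] - q[2], q[4] + q[2]),
    F_stat.energy = sum(v^2),
    F_stat.rms = sqrt(mean(v^2)),
    F_stat.entropy = .entropy2(p),
    F_stat.uniformity = sum(p^2))
}
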
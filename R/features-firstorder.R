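#' First-order (intensity histogram) features
#'
#' Eighteen descriptors of the ROI intensity distribution. Entropy and
#' uniformity are computed on the quantized gray-level histogram (levels
#' 1..n_levels); all other statistics use the included raw intensities.
#' Skewness and kurtosis use the population moment ratios `m3 / m2^1.5` and
#' `m4 / m2^2` (kurtosis not excess-corrected); both are 0 for a constant
#' ROI.
#'
#' @param qroi a [normalize_and_quantize()] result with at least 2 included
#'   voxels.
#' @return Named numeric vector of 18 features (`F_*`).
#' @export
first_order_features <- function(qroi) {
  x <- qroi$raw_values
  if (length(x) == 0) stop("all ROI voxels were excluded")
  lev <- qroi$levels[qroi$include]
  p <- tabulate(lev, nbins = qroi$n_levels) / length(lev)
  pnz <- p[p > 0]

  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  in_robust <- x >= q[1] & x <= q[5]

  c(F_Energy = sum(x^2),
    F_Entropy = -sum(pnz * log2(pnz)),
    F_Min = min(x),
    F_P10 = q[1],
    F_P90 = q[5],
    F_Max = max(x),
    F_Mean = mu,
    F_Median = q[3],
    F_IQR = q[4] - q[2],
    F_Range = max(x) - min(x),
    F_MAD = mean(abs(x - mu)),
    F_rMAD = mean(abs(x[in_robust] - mean(x[in_robust]))),
    F_RMS = sqrt(mean(x^2)),
    F_Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    F_Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    F_Variance = m2,
    F_Uniformity = sum(p^2),
    F_SD = sqrt(m2))
}
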
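#' Fixed-bin-width gray-level discretization
#'
#' Maps ROI intensities to integer gray levels with the fixed-bin-width rule
#' `bin = floor((x - min(x)) / bin_width) + 1`, so the number of levels
#' `n_levels` adapts to the ROI's intensity range. The offset is the ROI
#' minimum (per-ROI), applied after any whole-volume intensity
#' standardization.
#'
#' @param x Numeric vector of ROI voxel intensities (length >= 1).
#' @param bin_width Bin width in intensity units (> 0, default 25).
#' @return A list of class `discretized_roi`: `bins` (integer levels >= 1),
#'   `n_levels`, `bin_width`.
#' @export
#' @examples
#' discretize_roi(c(0, 24, 25, 50))$bins # 1 1 2 3
discretize_roi <- function(x, bin_width = 25) {
  if (length(x) < 1) stop("empty ROI")
  stopifnot(bin_width > 0, all(is.finite(x)))
  bins <- as.integer(floor((x - min(x)) / bin_width) + 1)
  structure(
    list(bins = bins, n_levels = max(bins), bin_width = bin_width),
    class = "discretized_roi"
  )
}

#' Histogram matching against a reference volume
#'
#' Standardizes image intensities by mapping the empirical distribution of
#' `volume` onto that of `reference` (quantile mapping over the full
#' empirical CDF, linear interpolation between reference order statistics).
#' Matching a volume against itself is the identity, and matching preserves
#' intensity ranks.
#'
#' @param volume Numeric array (or vector) to transform.
#' @param reference Numeric array providing the target distribution; must
#'   not be constant.
#' @return Array of the same shape as `volume`.
#' @export
histogram_match <- function(volume, reference) {
  if (length(volume) < 1 || length(reference) < 1) stop("empty volume")
  ref <- sort(as.numeric(reference))
  if (ref[1] == ref[length(ref)]) {
    stop("constant reference volume: histogram matching undefined")
  }
  x <- as.numeric(volume)
  ux <- sort(unique(x))
  # empirical CDF of the input at its unique values
  qx <- cumsum(tabulate(match(x, ux), nbins = length(ux))) / length(x)
  qr <- seq_along(ref) / length(ref)
  mapped <- stats::approx(qr, ref, xout = qx, rule = 2, ties = "ordered")$y
  out <- mapped[match(x, ux)]
  if (!is.null(dim(volume))) dim(out) <- dim(volume)
  out
}

#' First-order (intensity histogram) features
#'
#' The 18 first-order features of the catalogue. All are computed on the raw
#' intensities except `Entropy` and `Uniformity`, which use the discretized
#' histogram. Percentiles use linear interpolation between order statistics;
#' moments are population moments; skewness and kurtosis of a zero-variance
#' ROI are 0 by convention, and kurtosis is not excess-corrected (a normal
#' sample gives ~3).
#'
#' @param x Numeric vector of ROI intensities.
#' @param disc A [discretize_roi()] result for `x` (computed if `NULL`).
#' @param voxel_volume Volume of one voxel in mm^3 (for `TotalEnergy`).
#' @param bin_width Used when `disc` is `NULL`.
#' @return Named numeric vector of length 18 (`firstorder_*`).
#' @export
first_order_features <- function(x, disc = NULL, voxel_volume = 1,
                                 bin_width = 25) {
  if (length(x) < 1) stop("empty ROI")
  if (is.null(disc)) disc <- discretize_roi(x, bin_width)
  n <- length(x)
  p <- tabulate(disc$bins, nbins = disc$n_levels) / n
  p <- p[p > 0]
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9),
    names = FALSE,
    type = 7
  )
  m <- mean(x)
  m2 <- mean((x - m)^2)
  robust <- x[x >= q[1] & x <= q[5]]
  vals <- c(
    Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    TenthPercentile = q[1],
    NinetiethPercentile = q[5],
    Maximum = max(x),
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - m)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  stats::setNames(vals, paste0("firstorder_", names(vals)))
}
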
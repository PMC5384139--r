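#' Remove a least-squares linear trend
#'
#' Fits a straight line to the series by ordinary least squares and subtracts
#' it. This is the first step of the signal-conditioning chain applied to
#' every IMU channel before peak detection (detrend, normalize, band-pass).
#'
#' @param x Numeric vector (length >= 2, finite).
#' @return Numeric vector of the same length with the best-fit line removed;
#'   its mean is zero to numerical precision.
#' @examples
#' detrend_series(c(5, 5, 5, 5))   # all zeros
#' detrend_series(0:59)            # all zeros: a pure ramp is the trend
#' @export
detrend_series <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("detrend_series() needs at least 2 samples")
  if (!all(is.finite(x))) stop("detrend_series(): non-finite values")
  t <- seq_len(n)
  tm <- (n + 1) / 2
  slope <- sum((t - tm) * (x - mean(x))) / sum((t - tm)^2)
  x - (mean(x) + slope * (t - tm))
}

#' Scale a series to the unit interval by its peak magnitude
#'
#' Divides every sample by the maximum absolute value over the whole trial,
#' so that detector thresholds are expressed on a [-1, 1] scale independent
#' of sensor units or subject vigour. An all-zero series is returned
#' unchanged and flagged degenerate (attribute `degenerate = TRUE`) instead
#' of dividing by zero.
#'
#' @param x Numeric vector.
#' @return Numeric vector in [-1, 1]; `max(abs(result)) == 1` unless the
#'   input was all zeros.
#' @export
normalize_series <- function(x) {
  x <- as.numeric(x)
  m <- max(abs(x))
  if (m == 0) {
    attr(x, "degenerate") <- TRUE
    return(x)
  }
  x / m
}

butter_coeffs <- function(fs, f_low, f_high, order = 2L) {
  ny <- fs / 2
  if (!(f_low > 0 && f_low < f_high && f_high < ny))
    stop(sprintf("invalid band [%g, %g] Hz at fs = %g Hz (need 0 < low < high < Nyquist = %g)",
                 f_low, f_high, fs, ny))
  signal::butter(order, c(f_low, f_high) / ny, type = "pass")
}

#' Zero-phase Butterworth band-pass filter
#'
#' A 4th-order Butterworth band-pass (2 poles per band edge) applied forward
#' and backward so the net filter has zero phase: extrema and peaks are not
#' shifted in time, which is essential because activity peaks and transition
#' extrema are read off the filtered series. Edge transients are controlled
#' by odd-reflection padding (each end extended by the series mirrored
#' through its end point) before filtering.
#'
#' @param x Numeric vector.
#' @param fs Sample rate in Hz.
#' @param f_low Low cutoff in Hz (default 0.1).
#' @param f_high High cutoff in Hz; the transition-specific `f_cutoff`.
#' @return Filtered numeric vector, same length as `x`, zero mean.
#' @export
bandpass_filter <- function(x, fs, f_low = 0.1, f_high) {
  x <- as.numeric(x)
  n <- length(x)
  bf <- butter_coeffs(fs, f_low, f_high)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs)))
  if (pad < 3L) stop("series too short for band-pass filtering")
  head_ext <- 2 * x[1] - x[(pad + 1L):2L]
  tail_ext <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xe <- c(head_ext, x, tail_ext)
  # start each pass from the exact steady state for an input held at its
  # first value: a band-pass has zero DC gain, so past outputs are zero and
  # past inputs equal that value; this removes the step transient a filter
  # started from rest would add at each end
  run <- function(v) as.numeric(signal::filter(
    bf$b, bf$a, v,
    init.x = rep(v[1], length(bf$b) - 1L),
    init.y = rep(0, length(bf$a) - 1L)))
  y <- run(xe)
  y <- rev(run(rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Gain of the band-pass filter at a given frequency
#'
#' Squared magnitude response of the designed Butterworth band-pass (squared
#' because the filter is applied forward and backward). Used to predict
#' attenuation of out-of-band components.
#'
#' @inheritParams bandpass_filter
#' @param f Frequency (Hz) at which to evaluate the gain; vectorised.
#' @return Linear amplitude gain(s) of the zero-phase filter at `f`.
#' @export
bandpass_gain <- function(fs, f_low = 0.1, f_high, f) {
  bf <- butter_coeffs(fs, f_low, f_high)
  w <- 2 * pi * f / fs
  num <- vapply(w, function(wi) abs(sum(bf$b * exp(-1i * wi * (seq_along(bf$b) - 1)))), 0)
  den <- vapply(w, function(wi) abs(sum(bf$a * exp(-1i * wi * (seq_along(bf$a) - 1)))), 0)
  (num / den)^2
}

#' Central-difference time derivative
#'
#' Derivative with respect to time (units of `x` per second): central
#' differences in the interior, one-sided differences at the two ends.
#' Used for the thigh acceleration derivative whose sign separates standing
#' up from sitting down.
#'
#' @param x Numeric vector (length >= 3).
#' @param fs Sample rate in Hz.
#' @return Numeric vector, same length as `x`.
#' @export
series_derivative <- function(x, fs) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("series_derivative() needs at least 3 samples")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d
}

#' Histogram-bin threshold arithmetic
#'
#' The closed-form threshold computed from amplitude-histogram bin
#' statistics:
#' `threshold = bin_max - (bin_min - bin_width * alpha)`.
#' Kept as its own function so the arithmetic is exact and testable
#' independently of how the bin statistics are extracted from a histogram
#' (see [adaptive_threshold()]).
#'
#' @param bin_max,bin_min Amplitudes of the extreme occupied bins.
#' @param bin_width Common histogram bin width (> 0).
#' @param alpha Small relaxation factor (default 0.01).
#' @return The threshold amplitude.
#' @examples
#' eq1_threshold(0.975, 0.025, 0.05, 0.01)  # 0.9505
#' @export
eq1_threshold <- function(bin_max, bin_min, bin_width, alpha = 0.01) {
  stopifnot(bin_width > 0, bin_min <= bin_max, alpha >= 0, alpha <= 1)
  bin_max - (bin_min - bin_width * alpha)
}

#' Adaptive amplitude threshold from an equal-width histogram
#'
#' Builds an `n_bins` equal-width histogram of the absolute amplitudes and
#' derives a detection threshold via [eq1_threshold()]. The scheme adapts
#' the walking-detection limit to each subject's own signal amplitude
#' distribution (weak signals are common in Parkinsonian gait), in the same
#' spirit as Otsu's histogram thresholding.
#'
#' Two interpretations of the bin statistics are provided because the
#' defining phrase "maximum and minimum value of the bin" is ambiguous:
#' \describe{
#'   \item{`"centers"`}{(default) `bin_max`/`bin_min` are the center
#'     amplitudes of the highest and lowest *occupied* bins.}
#'   \item{`"edges"`}{the upper edge of the highest occupied bin and the
#'     lower edge of the lowest occupied bin.}
#' }
#'
#' @param x Numeric vector of amplitudes (absolute values are taken).
#' @param n_bins Number of histogram bins (default 20).
#' @param alpha Relaxation factor (default 0.01).
#' @param strategy Bin-statistic interpretation, `"centers"` or `"edges"`.
#' @return Threshold amplitude, within `[min(|x|), max(|x|) + bin_width]`.
#' @export
adaptive_threshold <- function(x, n_bins = 20L, alpha = 0.01,
                               strategy = c("centers", "edges")) {
  strategy <- match.arg(strategy)
  a <- abs(as.numeric(x))
  if (length(a) < n_bins) stop("adaptive_threshold() needs at least n_bins samples")
  rng <- range(a)
  if (diff(rng) <= 0) stop("adaptive_threshold(): degenerate (constant) amplitude range")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(a, breaks, rightmost.closed = TRUE), 1L), n_bins),
                     nbins = n_bins)
  occ <- which(counts > 0L)
  w <- breaks[2] - breaks[1]
  if (strategy == "centers") {
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    eq1_threshold(mids[max(occ)], mids[min(occ)], w, alpha)
  } else {
    eq1_threshold(breaks[max(occ) + 1L], breaks[min(occ)], w, alpha)
  }
}

#' Find local maxima above a height with a minimum separation
#'
#' Local maxima (ties broken to the earliest sample) with value at or above
#' `height`; among maxima closer together than `min_separation`, only the
#' largest survives (again ties to the earliest). This is the peak picker
#' applied to conditioned trunk/sacrum signals to locate activity peaks.
#'
#' @param x Numeric vector.
#' @param fs Sample rate in Hz.
#' @param height Minimum peak value.
#' @param min_separation Minimum spacing between reported peaks, seconds.
#' @return `data.frame` with columns `time` (s, 0-based: sample i has time
#'   `(i-1)/fs`) and `value`, sorted by time.
#' @export
find_peaks <- function(x, fs, height = -Inf, min_separation = 0) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(min_separation >= 0)
  if (n < 3) return(data.frame(time = numeric(0), value = numeric(0)))
  i <- 2:(n - 1)
  is_pk <- x[i] > x[i - 1] & x[i] >= x[i + 1]
  idx <- i[is_pk & x[i] >= height]
  if (length(idx) == 0) return(data.frame(time = numeric(0), value = numeric(0)))
  # greedy pruning: keep the tallest (earliest on ties), discard neighbours
  ord <- idx[order(-x[idx], idx)]
  keep <- integer(0)
  min_gap <- min_separation * fs
  for (j in ord) {
    if (all(abs(j - keep) >= min_gap)) keep <- c(keep, j)
  }
  keep <- sort(keep)
  data.frame(time = (keep - 1) / fs, value = x[keep])
}

#' Moving-RMS envelope
#'
#' Root-mean-square of the signal over a centered sliding window, used as
#' the oscillation envelope for gait-bout detection. Windows are truncated
#' at the series ends.
#'
#' @param x Numeric vector.
#' @param fs Sample rate in Hz.
#' @param window Window length in seconds (default 0.75, about one stride).
#' @return Numeric vector of envelope values, same length as `x`.
#' @export
moving_rms <- function(x, fs, window = 0.75) {
  x <- as.numeric(x)
  n <- length(x)
  half <- max(1L, as.integer(round(window * fs / 2)))
  cs <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

# centered moving average with truncated edge windows; cascaded after
# moving_rms in gait detection to suppress the stride-rate rectification
# ripple without widening the envelope support beyond one window
moving_avg <- function(x, fs, window = 0.75) {
  n <- length(x)
  half <- max(1L, as.integer(round(window * fs / 2)))
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
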
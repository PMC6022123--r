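# Whole-walk signal descriptors. Moment conventions used throughout:
# population (divide-by-n) variance and standardized moments, non-excess
# kurtosis (a Gaussian series has kurtosis 3). Quantities undefined for a
# degenerate input (zero variance, single-bin spectrum, < 2 intervals) return
# NaN here; extract_features() maps NaN to 0 under the missing-value policy.

popvar <- function(x) mean((x - mean(x))^2)

#' Poincare plot dispersion descriptors SD1/SD2
#'
#' Scatter the series against its lag-`lag` self and measure dispersion
#' perpendicular to the line of identity (SD1, short-term variability) and
#' along it (SD2). Computed from the rotated coordinates: with pairs
#' `(x_i, x_{i+lag})`, `sd1 = sqrt(popvar(x_i - x_{i+lag}) / 2)` and
#' `sd2 = sqrt(popvar(x_i + x_{i+lag}) / 2)`, population variance over the
#' paired range.
#'
#' @param x numeric series of length `>= lag + 2`.
#' @param lag positive integer lag (default 1).
#' @return List with `sd1` and `sd2` (both `>= 0`), class
#'   `poincare_descriptors`.
#' @export
poincare_descriptors <- function(x, lag = 1L) {
  n <- length(x)
  if (n < lag + 2L) abort_hg("series too short for Poincare pairs", "hemigait_validation_error")
  a <- x[seq_len(n - lag)]
  b <- x[seq_len(n - lag) + lag]
  structure(
    list(sd1 = sqrt(popvar(a - b) / 2), sd2 = sqrt(popvar(a + b) / 2)),
    class = "poincare_descriptors"
  )
}

#' Shape moments of the one-sided power spectrum
#'
#' Removes the mean, takes the rectangular-window periodogram, drops the DC
#' bin, and normalises the remaining one-sided power to a probability mass
#' function over frequency. Reported are the dominant frequency (argmax bin),
#' spectral centroid, bandwidth (SD of the spectral mass), spectral skewness
#' and kurtosis (standardized 3rd/4th moments, non-excess), spectral entropy
#' (natural log), and the pre-normalisation total power (scaled so that it
#' approximates the series' population variance, by Parseval). A single-bin
#' spectrum has bandwidth 0; its skewness is reported as 0 and its kurtosis as
#' `NaN`.
#'
#' @param x numeric series, length >= 8.
#' @param fs sampling rate in Hz.
#' @return List of class `spectral_moments` with fields `dominant_freq`,
#'   `centroid`, `bandwidth`, `skew`, `kurt`, `entropy`, `total_power`.
#' @export
spectral_moments <- function(x, fs) {
  n <- length(x)
  if (n < 8L) abort_hg("series too short for a spectrum", "hemigait_validation_error")
  x <- x - mean(x)
  X <- stats::fft(x)
  half <- n %/% 2L
  k <- seq_len(half)                       # DC (k = 0) excluded
  pw <- Mod(X[k + 1L])^2 / n^2
  double_ok <- k < n / 2                   # Nyquist bin (even n) not doubled
  pw[double_ok] <- 2 * pw[double_ok]
  freq <- k * fs / n
  total <- sum(pw)
  if (total <= 0) {
    abort_hg("zero total power: constant input has no spectral mass",
             "hemigait_degenerate_error")
  }
  sm <- spectral_moments_from_pmf(freq, pw / total)
  sm$dominant_freq <- freq[which.max(pw)]
  sm$total_power <- total
  structure(sm[c("dominant_freq", "centroid", "bandwidth", "skew", "kurt",
                 "entropy", "total_power")], class = "spectral_moments")
}

#' Moments of an arbitrary spectral probability mass function
#'
#' The moment stage of [spectral_moments()], exposed so the moments can be
#' computed for any discrete distribution over frequency.
#'
#' @param freq numeric vector of frequencies.
#' @param p probability masses, same length, summing to 1.
#' @return List with `centroid`, `bandwidth`, `skew`, `kurt`, `entropy`.
#' @export
spectral_moments_from_pmf <- function(freq, p) {
  stopifnot(length(freq) == length(p))
  centroid <- sum(freq * p)
  m2 <- sum((freq - centroid)^2 * p)
  bandwidth <- sqrt(m2)
  # single-bin spectra carry numerically negligible off-bin mass (FFT
  # leakage at ~1e-15 relative); treat bandwidth below 1e-9 of the frequency
  # scale as zero rather than dividing by it
  if (bandwidth > 1e-9 * max(abs(freq))) {
    skew <- sum((freq - centroid)^3 * p) / m2^1.5
    kurt <- sum((freq - centroid)^4 * p) / m2^2
  } else {
    skew <- 0
    kurt <- NaN
  }
  nz <- p > 0
  entropy <- -sum(p[nz] * log(p[nz]))
  list(centroid = centroid, bandwidth = bandwidth, skew = skew, kurt = kurt,
       entropy = entropy)
}

#' Zero-crossing count and crossing-interval statistics
#'
#' The series is mean-removed first. A crossing occurs between samples
#' `i, i+1` when the signs differ; exact zeros carry the previous sign.
#' Intervals are the times (s) between consecutive crossing indices. With
#' fewer than two crossings the mean and SD intervals are 0 by convention.
#'
#' @param x numeric series, length >= 2.
#' @param fs sampling rate in Hz.
#' @return List `n_crossings`, `mean_interval_s`, `sd_interval_s`.
#' @export
crossing_stats <- function(x, fs) {
  if (length(x) < 2L) abort_hg("series too short", "hemigait_validation_error")
  x <- x - mean(x)
  s <- sign(x)
  # zeros inherit the previous sign (leading zeros: the first nonzero sign)
  nz <- s != 0
  if (!any(nz)) {
    return(list(n_crossings = 0L, mean_interval_s = 0, sd_interval_s = 0))
  }
  first_nz <- which(nz)[1L]
  if (first_nz > 1L) s[seq_len(first_nz - 1L)] <- s[first_nz]
  s <- cummaxfill_sign(s)
  cross_at <- which(s[-1L] * s[-length(s)] < 0) + 1L
  ints <- diff(cross_at) / fs
  list(
    n_crossings = length(cross_at),
    mean_interval_s = if (length(ints) >= 1L) mean(ints) else 0,
    sd_interval_s = if (length(ints) >= 1L) sqrt(popvar(ints)) else 0
  )
}

# forward-fill zero signs with the previous nonzero sign
cummaxfill_sign <- function(s) {
  z <- s == 0
  if (!any(z)) return(s)
  idx <- seq_along(s)
  idx[z] <- 0L
  idx <- cummax(idx)
  s[idx]
}

#' Local-maxima count and peak-interval statistics
#'
#' Strict local maxima (`x[i-1] < x[i] > x[i+1]`); a flat-topped plateau
#' counts once at its first index. Intervals are the times (s) between
#' consecutive maxima; with fewer than two maxima the mean and SD are 0 by
#' convention.
#'
#' @param x numeric series, length >= 3.
#' @param fs sampling rate in Hz.
#' @return List `n_peaks`, `mean_interval_s`, `sd_interval_s`.
#' @export
peak_interval_stats <- function(x, fs) {
  n <- length(x)
  if (n < 3L) abort_hg("series too short", "hemigait_validation_error")
  d <- diff(x)
  # a peak starts where the previous strict move is up and the next strict
  # move (skipping any plateau) is down
  peaks <- integer(0)
  nzd <- which(d != 0)
  if (length(nzd) >= 2L) {
    up_then_down <- d[nzd[-length(nzd)]] > 0 & d[nzd[-1L]] < 0
    peaks <- nzd[-length(nzd)][up_then_down] + 1L   # first index of the plateau
  }
  ints <- diff(peaks) / fs
  list(
    n_peaks = length(peaks),
    mean_interval_s = if (length(ints) >= 1L) mean(ints) else 0,
    sd_interval_s = if (length(ints) >= 1L) sqrt(popvar(ints)) else 0
  )
}

#' Time-domain summary moments of a series
#'
#' Population conventions: `sd = sqrt(mean((x - mean)^2))`, kurtosis
#' non-excess (Gaussian -> 3). A zero-variance series has `NaN` kurtosis and
#' skewness.
#'
#' @param x numeric series, length >= 2.
#' @return List `mean`, `max`, `min`, `range`, `sd`, `var`, `rms`,
#'   `kurtosis`, `skewness`.
#' @export
basic_stats <- function(x) {
  if (length(x) < 2L) abort_hg("series too short", "hemigait_validation_error")
  mu <- mean(x)
  v <- popvar(x)
  list(
    mean = mu, max = max(x), min = min(x), range = max(x) - min(x),
    sd = sqrt(v), var = v, rms = sqrt(mean(x^2)),
    kurtosis = if (v > 0) mean((x - mu)^4) / v^2 else NaN,
    skewness = if (v > 0) mean((x - mu)^3) / v^1.5 else NaN
  )
}

#' Autocorrelation summaries
#'
#' Lag-1 autocorrelation and the height of the first local maximum of the
#' autocorrelation function at nonzero lag (the classic step/stride
#' regularity index for trunk signals). Autocorrelation is the biased
#' (divide-by-n) normalised estimate. With no local maximum in the searched
#' range, the peak height is `NaN`.
#'
#' @param x numeric series, length >= 3.
#' @param max_lag_s maximum lag searched for the first peak, in seconds
#'   (default 3 s, beyond any plausible stride time).
#' @param fs sampling rate in Hz.
#' @return List `ac1`, `first_peak_height`.
#' @export
autocorr_stats <- function(x, fs, max_lag_s = 3) {
  n <- length(x)
  if (n < 3L) abort_hg("series too short", "hemigait_validation_error")
  if (popvar(x) == 0) return(list(ac1 = NaN, first_peak_height = NaN))
  max_lag <- min(n - 2L, as.integer(round(max_lag_s * fs)))
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  # ac[1] is lag 0
  ac1 <- ac[2L]
  r <- ac[-1L]
  pk <- NaN
  if (length(r) >= 3L) {
    loc <- which(diff(sign(diff(r))) == -2L) + 1L
    if (length(loc)) pk <- r[loc[1L]]
  }
  list(ac1 = ac1, first_peak_height = pk)
}
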
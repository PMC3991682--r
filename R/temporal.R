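# Temporal descriptors of a component time course: moments/entropy/mean,
# periodogram-based spectral band powers and high-frequency fraction, extrema
# and min-to-max jump statistics, lag-1..5 autocorrelations, and dynamic
# spectral range/count metrics.

#' Time-course moments, entropy and mean
#'
#' Same estimator conventions as [map_moments()] (population moments, Pearson
#' kurtosis, 100-bin Shannon entropy with natural log), plus the arithmetic
#' mean of the series.
#'
#' @param timecourse Numeric vector, length >= 3.
#' @return Named vector `(kurtosis, skewness, entropy, mean)`.
#' @export
tc_moments <- function(timecourse) {
  if (length(timecourse) < 3L) nc_abort("time course too short (T < 3)", "input")
  me <- moments_entropy(timecourse, what = "series")
  c(me, mean = mean(timecourse))
}

#' Mean-removed periodogram of a time course
#'
#' Plain periodogram (no tapering or segment averaging): the squared modulus
#' of the DFT of the mean-removed series at the one-sided frequencies
#' 0..Nyquist, normalized so the total power is 1. The DC bin has zero mass
#' after mean removal.
#'
#' @param timecourse Numeric vector, length >= 8.
#' @param tr Sampling interval in seconds.
#' @return An `nc_spectrum`: tibble with columns `freq` (Hz) and `power`
#'   (fractions summing to 1), plus attributes `tr` and `nyquist`.
#' @export
periodogram <- function(timecourse, tr) {
  tt <- length(timecourse)
  if (tt < 8L) nc_abort("time course too short for a spectrum (T < 8)", "input")
  if (tr <= 0) nc_abort("`tr` must be positive", "input")
  x <- timecourse - mean(timecourse)
  ft <- stats::fft(x)
  n_half <- floor(tt / 2)
  idx <- seq_len(n_half + 1L)          # bins 0..Nyquist(ish)
  pw <- Mod(ft[idx])^2
  total <- sum(pw)
  if (total == 0) nc_abort("constant series has no spectrum", "degenerate")
  pw <- pw / total
  freq <- (idx - 1L) / (tt * tr)
  out <- tibble::tibble(freq = freq, power = pw)
  attr(out, "tr") <- tr
  attr(out, "nyquist") <- 1 / (2 * tr)
  class(out) <- c("nc_spectrum", class(out))
  out
}

#' The five canonical resting-state frequency bands
#'
#' Band edges in Hz: 0-0.008, 0.008-0.02, 0.02-0.05, 0.05-0.1, 0.1-0.25.
#' Membership is half-open `[lo, hi)` so no frequency belongs to two bands.
#' @return Data frame with columns `lo`, `hi`, `id`.
#' @export
power_bands <- function() {
  tibble::tibble(
    lo = c(0, 0.008, 0.02, 0.05, 0.1),
    hi = c(0.008, 0.02, 0.05, 0.1, 0.25),
    id = c("power_band_0_0.008", "power_band_0.008_0.02",
           "power_band_0.02_0.05", "power_band_0.05_0.1",
           "power_band_0.1_0.25")
  )
}

#' Fraction of spectral power in each canonical band
#'
#' Bins above 0.25 Hz belong to no band but stay in the normalizing total, so
#' the five fractions sum to at most 1.
#'
#' @param spectrum An `nc_spectrum`.
#' @return Named numeric vector of 5 fractions.
#' @export
band_power <- function(spectrum) {
  bands <- power_bands()
  out <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- spectrum$freq >= bands$lo[[i]] & spectrum$freq < bands$hi[[i]]
    sum(spectrum$power[sel])
  }, 0)
  names(out) <- bands$id
  out
}

#' Fraction of spectral power above a cutoff frequency
#'
#' @param spectrum An `nc_spectrum`.
#' @param cutoff Cutoff in Hz (default 0.1, the upper edge of the canonical
#'   resting-state bands); power at frequencies strictly above it counts.
#' @return Fraction in [0, 1].
#' @export
high_freq_fraction <- function(spectrum, cutoff = 0.1) {
  sum(spectrum$power[spectrum$freq > cutoff])
}

#' Extrema and jump statistics of a time course
#'
#' Interior strict local extrema (each sample compared with both neighbors;
#' plateau points are not extrema). Distances are the mean gap in time points
#' between consecutive maxima (resp. minima); jumps are the amplitude
#' differences for each adjacent minimum-to-maximum pair in the time-ordered
#' merged extrema sequence. A series with no interior extrema returns all
#' zeros.
#'
#' @param timecourse Numeric vector, length >= 3.
#' @return Named vector `(n_maxima, n_minima, avg_dist_maxima,
#'   avg_dist_minima, avg_jump, biggest_jump)`.
#' @export
extrema_metrics <- function(timecourse) {
  tt <- length(timecourse)
  if (tt < 3L) nc_abort("time course too short (T < 3)", "input")
  x <- timecourse
  i <- 2:(tt - 1L)
  is_max <- x[i] > x[i - 1L] & x[i] > x[i + 1L]
  is_min <- x[i] < x[i - 1L] & x[i] < x[i + 1L]
  max_idx <- i[is_max]
  min_idx <- i[is_min]
  avg_gap <- function(idx) if (length(idx) >= 2L) mean(diff(idx)) else 0

  ext_idx <- sort(c(max_idx, min_idx))
  ext_is_max <- ext_idx %in% max_idx
  jumps <- numeric(0)
  if (length(ext_idx) >= 2L) {
    k <- seq_len(length(ext_idx) - 1L)
    pair <- !ext_is_max[k] & ext_is_max[k + 1L]   # min followed by max
    jumps <- x[ext_idx[k + 1L][pair]] - x[ext_idx[k][pair]]
  }
  c(
    n_maxima = length(max_idx),
    n_minima = length(min_idx),
    avg_dist_maxima = avg_gap(max_idx),
    avg_dist_minima = avg_gap(min_idx),
    avg_jump = if (length(jumps)) mean(jumps) else 0,
    biggest_jump = if (length(jumps)) max(jumps) else 0
  )
}

#' Lag-1..5 autocorrelations
#'
#' Pearson correlation between the series and its lag-k shift.
#'
#' @param timecourse Numeric vector.
#' @param lags Integer lags (default 1:5); requires `T >= max(lags) + 6`.
#' @return Named vector of correlations in [-1, 1].
#' @export
autocorrelation <- function(timecourse, lags = 1:5) {
  tt <- length(timecourse)
  if (tt < max(lags) + 6L) nc_abort("time course too short for requested lags", "input")
  if (stats::sd(timecourse) == 0) nc_abort("constant series", "degenerate")
  out <- vapply(lags, function(k) {
    a <- timecourse[seq_len(tt - k)]
    b <- timecourse[(k + 1L):tt]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }, 0)
  names(out) <- paste0("autocorr_lag", lags)
  out
}

#' Dynamic spectral range and count metrics
#'
#' Let f* be the frequency of maximal power. The high-side dynamic range is
#' peak power minus the minimum power at frequencies above f* (0 if none);
#' the low-side range is the analogue below f*. The "count" variants apply
#' the same computation to the spectrum re-aggregated into 32 equal-width
#' frequency bins spanning 0..Nyquist.
#'
#' @param spectrum An `nc_spectrum` with >= 3 bins.
#' @return Named vector `(dyn_range_low, dyn_range_high, dyn_count_diff_low,
#'   dyn_count_diff_high)`, all >= 0.
#' @export
dynamic_spectrum_metrics <- function(spectrum) {
  if (nrow(spectrum) < 3L) nc_abort("spectrum needs at least 3 bins", "input")
  rng <- peak_side_ranges(spectrum$freq, spectrum$power)
  nyq <- attr(spectrum, "nyquist") %||% max(spectrum$freq)
  edges <- seq(0, nyq, length.out = 33L)
  bin <- findInterval(spectrum$freq, edges, rightmost.closed = TRUE, all.inside = TRUE)
  # mean (not sum) per bin: equal-width bins cover unequal numbers of raw
  # frequencies, and averaging keeps a flat spectrum flat after aggregation
  agg <- vapply(seq_len(32L), function(b) {
    sel <- bin == b
    if (any(sel)) mean(spectrum$power[sel]) else 0
  }, 0)
  centers <- (edges[-1] + edges[-33]) / 2
  cnt <- peak_side_ranges(centers, agg)
  c(
    dyn_range_low = rng[["low"]],
    dyn_range_high = rng[["high"]],
    dyn_count_diff_low = cnt[["low"]],
    dyn_count_diff_high = cnt[["high"]]
  )
}

peak_side_ranges <- function(freq, power) {
  i_star <- which.max(power)
  p_star <- power[[i_star]]
  lo <- if (i_star > 1L) p_star - min(power[seq_len(i_star - 1L)]) else 0
  hi <- if (i_star < length(power)) p_star - min(power[(i_star + 1L):length(power)]) else 0
  c(low = lo, high = hi)
}
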
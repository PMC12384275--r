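# Shared numeric helpers: linear detrend, local-maxima picking with
# minimum-separation and parabolic refinement, Gaussian kernel smoothing,
# and a Hann-windowed zero-padded periodogram with band-restricted peak pick.

#' Linear least-squares detrend
#'
#' Removes the best-fitting straight line (intercept + slope) from a series.
#' Idempotent: detrending twice equals detrending once.
#'
#' @param x Numeric vector.
#' @return Numeric vector of residuals around the fitted line.
#' @keywords internal
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) return(x - mean(x))
  t <- seq_len(n)
  t <- t - mean(t)
  slope <- sum(t * x) / sum(t * t)
  x - mean(x) - slope * t
}

#' Local maxima with a minimum separation
#'
#' Finds strict local maxima, then enforces a minimum index separation by
#' greedily keeping the taller peak of any conflicting pair. Optionally refines
#' each peak's height (and sub-sample position) by fitting a parabola through
#' the three samples around the maximum.
#'
#' @param x Numeric vector.
#' @param min_sep Minimum separation between kept peaks, in samples.
#' @param refine Logical; parabolic refinement of heights/positions.
#' @return A list with `index` (integer sample indices), `pos` (possibly
#'   fractional positions, in samples) and `height` (refined heights).
#' @keywords internal
find_peaks <- function(x, min_sep = 1, refine = TRUE) {
  n <- length(x)
  empty <- list(index = integer(0), pos = numeric(0), height = numeric(0))
  if (n < 3L) return(empty)
  core <- x[2:(n - 1L)]
  cand <- which(core > x[1:(n - 2L)] & core >= x[3:n]) + 1L
  if (!length(cand)) return(empty)
  if (min_sep > 1 && length(cand) > 1L) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    keep <- logical(0)
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  pos <- as.numeric(cand)
  height <- x[cand]
  if (refine) {
    ok <- cand > 1L & cand < n
    a <- x[cand[ok] - 1L]; b <- x[cand[ok]]; c <- x[cand[ok] + 1L]
    denom <- a - 2 * b + c
    delta <- ifelse(abs(denom) > .Machine$double.eps, 0.5 * (a - c) / denom, 0)
    delta <- pmax(pmin(delta, 0.5), -0.5)
    pos[ok] <- cand[ok] + delta
    height[ok] <- b - 0.25 * (a - c) * delta
    height <- pmax(height, x[cand])  # envelope must not undercut the sample
  }
  list(index = cand, pos = pos, height = height)
}

#' Gaussian kernel smoothing
#'
#' Smooths a uniformly sampled series with a truncated (±4 sd) Gaussian
#' kernel, renormalising the kernel at the edges so the output has no edge
#' droop.
#'
#' @param x Numeric vector sampled at `fs`.
#' @param sd_s Kernel standard deviation, seconds.
#' @param fs Sampling rate, Hz.
#' @return Smoothed numeric vector, same length as `x`.
#' @keywords internal
smooth_gaussian <- function(x, sd_s, fs) {
  sd_n <- sd_s * fs
  if (sd_n < 0.25) return(x)
  half <- max(1L, as.integer(ceiling(4 * sd_n)))
  k <- stats::dnorm(seq(-half, half), sd = sd_n)
  num <- stats::filter(x, k, sides = 2)
  den <- stats::filter(rep(1, length(x)), k, sides = 2)
  out <- as.numeric(num / den)
  # stats::filter leaves NA where the kernel overruns; renormalise manually
  na <- which(is.na(out))
  for (i in na) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    w <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(x[lo:hi] * w) / sum(w)
  }
  out
}

#' Hann-windowed zero-padded periodogram with band-restricted peak
#'
#' Removes the mean, applies a Hann window, zero-pads to at least `nfft`
#' points (rounded up to a power of two) and returns the power spectrum
#' together with the location of the maximum inside `band`. Frequency ties
#' break toward the lower frequency (harmonics sit above the fundamental).
#'
#' @param x Numeric vector, uniformly sampled.
#' @param fs Sampling rate, Hz.
#' @param band Length-2 numeric, the search band in Hz.
#' @param df_max Maximum acceptable frequency-grid spacing, Hz. The FFT length
#'   is padded until the grid is at least this fine.
#' @return List with `freq`, `power` (full one-sided spectrum), `peak_hz`
#'   (NA if the band is empty or has zero power), `is_local_max` (whether the
#'   band argmax is a genuine spectral peak rather than the clipped slope of
#'   an out-of-band peak), `band_power`, `total_power`.
#' @export
psd_band_peak <- function(x, fs, band, df_max = fs / 2^16) {
  n <- length(x)
  stopifnot(n >= 4L, is.finite(fs), fs > 0, length(band) == 2L)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- x * w
  nfft <- 2^ceiling(log2(max(n, ceiling(fs / df_max))))
  X <- stats::fft(c(xw, numeric(nfft - n)))
  half <- seq_len(nfft %/% 2 + 1L)
  power <- Mod(X[half])^2
  freq <- (half - 1L) * fs / nfft
  in_band <- which(freq >= band[1] & freq <= band[2])
  total_power <- sum(power)
  if (!length(in_band) || total_power == 0) {
    return(list(freq = freq, power = power, peak_hz = NA_real_,
                band_power = 0, total_power = total_power))
  }
  bp <- power[in_band]
  imax <- in_band[which.max(bp)]
  peak_hz <- if (max(bp) <= 0) NA_real_ else freq[imax]
  # is the band argmax a genuine spectral peak (not the clipped slope of a
  # peak outside the band)?
  is_local_max <- !is.na(peak_hz) && imax > 1L && imax < length(power) &&
    power[imax] > power[imax - 1L] && power[imax] >= power[imax + 1L]
  list(freq = freq, power = power, peak_hz = peak_hz,
       is_local_max = is_local_max,
       band_power = sum(bp), total_power = total_power)
}

# argument check helper: scalar finite numeric
check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
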
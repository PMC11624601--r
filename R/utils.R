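#' Amplitude envelope via the analytic signal
#'
#' Computes `|x + i * H(x)|`, the magnitude of the analytic signal, where the
#' Hilbert transform is applied in the frequency domain.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length, the instantaneous amplitude.
#' @export
envelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Root-mean-square of a vector
#' @param x numeric vector.
#' @return scalar RMS.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Raised-cosine onset/offset ramp
#'
#' Multiplies the first and last `ramp_ms` of a signal by half-cosine ramps.
#'
#' @param x numeric vector of samples.
#' @param ramp_ms ramp duration in ms.
#' @param rate sample rate in Hz.
#' @return ramped copy of `x`.
#' @export
apply_ramp <- function(x, ramp_ms, rate) {
  nr <- round(ramp_ms / 1000 * rate)
  if (nr < 1L || 2L * nr > length(x)) return(x)
  w <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
  x[seq_len(nr)] <- x[seq_len(nr)] * w
  x[(length(x) - nr + 1L):length(x)] <- x[(length(x) - nr + 1L):length(x)] * rev(w)
  x
}

#' Normalized autocorrelation of a vector
#' @param x numeric vector.
#' @param max_lag maximum lag in samples.
#' @return vector of autocorrelations at lags `0:max_lag`.
#' @export
autocorr <- function(x, max_lag) {
  x <- x - mean(x)
  denom <- sum(x^2)
  vapply(0:max_lag, function(l) {
    n <- length(x)
    sum(x[1:(n - l)] * x[(1 + l):n]) / denom
  }, numeric(1))
}

# First local maximum of the autocorrelation away from lag 0; returns lag in
# samples, used to estimate envelope periodicity.
first_ac_peak <- function(ac, min_lag = 2L) {
  n <- length(ac) - 1L                    # ac covers lags 0..n
  lag <- seq_along(ac) - 1L
  cand <- which(lag >= min_lag)
  is_peak <- vapply(cand, function(i) {
    i > 1L && i < length(ac) && ac[i] >= ac[i - 1L] && ac[i] >= ac[i + 1L]
  }, logical(1))
  peaks <- cand[is_peak]
  if (length(peaks) == 0L) return(NA_integer_)
  # first peak that is a substantial fraction of the global post-lag maximum
  thr <- 0.5 * max(ac[peaks])
  lag[peaks[which(ac[peaks] >= thr)[1]]]
}

#' Estimate the fundamental frequency of a waveform from its envelope
#'
#' Computes the amplitude envelope (analytic-signal magnitude, smoothed with a
#' short moving average to suppress carrier ripple), takes its normalized
#' autocorrelation, and returns the frequency corresponding to the first major
#' peak: the global autocorrelation maximum over candidate period lags,
#' refined by parabolic interpolation.
#'
#' @param w a `waveform`.
#' @param min_period,max_period candidate period range, ms.
#' @param smooth_ms moving-average length for envelope smoothing, ms.
#' @return list with `f0` (Hz), `period` (ms) and `ac` (the autocorrelation
#'   value at the peak).
#' @export
estimate_f0 <- function(w, min_period = 4, max_period = 30, smooth_ms = 1.5) {
  env <- envelope(w$samples)
  ns <- max(1L, round(smooth_ms / 1000 * w$rate))
  env <- as.vector(stats::filter(env, rep(1 / ns, ns), sides = 2))
  env <- env[!is.na(env)]
  max_lag <- round(max_period / 1000 * w$rate)
  ac <- autocorr(env, max_lag)
  lags <- 0:max_lag
  sel <- lags >= round(min_period / 1000 * w$rate)
  i <- which(sel)[which.max(ac[sel])]
  lag <- lags[i]
  if (i > 1L && i < length(ac)) {          # parabolic peak refinement
    y1 <- ac[i - 1]; y2 <- ac[i]; y3 <- ac[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / denom
  }
  period <- lag / w$rate * 1000
  list(f0 = 1000 / period, period = period, ac = ac[i])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a child seed from a base seed and an index, staying within 32-bit
# integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1009) %% 2147483647)
}
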
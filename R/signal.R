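#' Construct a uniformly sampled one-dimensional signal
#'
#' Container for a raw sensor stream (e.g. a PPG trace): a numeric amplitude
#' vector with its sampling rate and the session-relative start time.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units), length >= 2,
#'   all finite.
#' @param rate Sampling rate in Hz, > 0.
#' @param start_time Time of the first sample in seconds (default 0).
#' @return An object of class `raw_signal` with elements `samples`, `rate`,
#'   `start_time`.
#' @export
raw_signal <- function(samples, rate, start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("raw_signal: need at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("raw_signal: all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("raw_signal: sampling rate must be a positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = as.numeric(rate),
         start_time = as.numeric(start_time)),
    class = "raw_signal"
  )
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %d samples @ %g Hz (%.2f s), start %.2f s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              x$start_time))
  invisible(x)
}

#' @export
length.raw_signal <- function(x) length(x$samples)

#' Time stamps of a raw_signal's samples, in seconds
#' @param signal A `raw_signal`.
#' @return Numeric vector of sample times.
#' @export
signal_times <- function(signal) {
  signal$start_time + (seq_along(signal$samples) - 1L) / signal$rate
}

#' Zero-mean unit-variance normalization
#'
#' Standardizes a signal to mean 0 and population standard deviation 1. This is
#' the first step of the PPG preprocessing chain, making amplitudes comparable
#' across recordings and sensor gains.
#'
#' @param signal A `raw_signal` with non-zero variance.
#' @return A `raw_signal` of the same length and rate with mean 0, SD 1.
#' @export
normalize_signal <- function(signal) {
  stopifnot(inherits(signal, "raw_signal"))
  x <- signal$samples
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2)) # population SD
  if (sdev <= 0 || !is.finite(sdev)) {
    stop("normalize_signal: degenerate signal (zero variance)", call. = FALSE)
  }
  raw_signal((x - mu) / sdev, signal$rate, signal$start_time)
}

#' Hampel outlier filter
#'
#' Replaces samples that deviate from the local median by more than
#' `n_sigmas` robust standard deviations (1.4826 x local MAD) with that local
#' median. Outliers are replaced, not deleted, so uniform sampling is
#' preserved for the downstream band-pass filter. Window edges use truncated
#' windows so every sample is screened.
#'
#' @param signal A `raw_signal`.
#' @param half_window Half-width of the centered window in samples (default 5,
#'   i.e. an 11-sample neighborhood around each sample).
#' @param n_sigmas Rejection threshold in robust SDs (default 3).
#' @return Filtered `raw_signal`, same length and rate.
#' @export
hampel_filter <- function(signal, half_window = 5L, n_sigmas = 3) {
  stopifnot(inherits(signal, "raw_signal"))
  half_window <- as.integer(half_window)
  if (half_window < 1L) {
    stop("hampel_filter: half_window must be >= 1", call. = FALSE)
  }
  x <- signal$samples
  n <- length(x)
  if (2L * half_window + 1L > n) {
    stop("hampel_filter: window longer than signal", call. = FALSE)
  }
  y <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_window)
    hi <- min(n, i + half_window)
    w <- x[lo:hi]
    m <- stats::median(w)
    s <- 1.4826 * stats::median(abs(w - m))
    if (is.finite(s) && abs(x[i] - m) > n_sigmas * s) {
      y[i] <- m
    }
  }
  raw_signal(y, signal$rate, signal$start_time)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass design forward and backward
#' (`signal::filtfilt`), so landmarks are not shifted in time and the
#' effective magnitude response is the squared one-pass response. Defaults
#' retain the cardiac band 0.5-4.0 Hz (30-240 bpm) of a PPG trace.
#'
#' @param signal A `raw_signal`.
#' @param low Low cutoff in Hz (default 0.5).
#' @param high High cutoff in Hz (default 4.0).
#' @param order Filter (prototype) order, default 4.
#' @return Filtered `raw_signal`, same length and rate.
#' @export
bandpass_filter <- function(signal, low = 0.5, high = 4.0, order = 4L) {
  stopifnot(inherits(signal, "raw_signal"))
  nyq <- signal$rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("bandpass_filter: need 0 < low < high < Nyquist", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  y <- filtfilt_padded(bf, signal$samples, pad = round(3 * signal$rate / low))
  raw_signal(y, signal$rate, signal$start_time)
}

# forward-backward filtering with edge-reflected padding, so start/end
# transients do not leak into the retained samples
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(as.numeric(signal::filtfilt(bf, x)))
  pre <- 2 * x[1L] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(pad + 1L):(pad + n)]
}

#' Analytic squared Butterworth band-pass magnitude response
#'
#' Amplitude gain expected from the forward-backward (zero-phase) application
#' of the digital Butterworth band-pass: the squared analog magnitude
#' response evaluated at the bilinear-transform prewarped frequency.
#'
#' @param f Probe frequency in Hz.
#' @param rate Sampling rate in Hz.
#' @param low,high Band edges in Hz.
#' @param order Prototype order.
#' @return Expected amplitude gain (|H|^2 of one pass).
#' @export
butter_bandpass_gain <- function(f, rate, low = 0.5, high = 4.0, order = 4L) {
  warp <- function(fr) (rate / pi) * tan(pi * fr / rate)
  wl <- warp(low); wh <- warp(high); w <- warp(f)
  u <- (w^2 - wl * wh) / (w * (wh - wl))
  (1 / (1 + u^(2 * order)))
}
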
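#' Per-cycle temporal (morphological) features
#'
#' Shape descriptors of one quality-screened cardiac cycle. The documented
#' set (17 features): cycle duration; systolic upstroke time (valley to
#' peak); diastolic time (peak to valley); upstroke fraction
#' (upstroke/duration); peak amplitude over the cycle baseline; widths at
#' 25/50/75% of peak amplitude; area under the cycle above baseline; half-
#' and quarter-decay times after the peak; diastolic area fraction; max and
#' min of the first and second derivative. Landmark-based times use the
#' detector's sub-sample refined positions; widths and decay times use
#' linearly interpolated level crossings.
#'
#' @param cycle A `cardiac_cycle`.
#' @return Named numeric vector of length 17.
#' @export
extract_temporal_features <- function(cycle) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  seg <- cycle$segment
  rate <- cycle$rate
  n <- length(seg)
  baseline <- min(seg)
  pk_rel <- cycle$systolic_peak - cycle$valley_start + 1L
  amplitude <- seg[pk_rel] - baseline
  if (amplitude <= sqrt(.Machine$double.eps)) {
    stop("extract_temporal_features: degenerate (flat) cycle", call. = FALSE)
  }
  duration <- cycle$duration
  # refined sub-sample landmark times when the detector provides them
  if (!is.null(cycle$t_peak)) {
    upstroke <- cycle$t_peak - cycle$start_time
    diastolic <- cycle$t_end - cycle$t_peak
  } else {
    upstroke <- (pk_rel - 1L) / rate
    diastolic <- (n - pk_rel) / rate
  }
  width_at <- function(frac) {
    level <- baseline + frac * amplitude
    above <- which(seg >= level)
    if (length(above) == 0L) return(0)
    i1 <- above[1L]; i2 <- above[length(above)]
    p1 <- if (i1 > 1L) {
      i1 - 1 + (level - seg[i1 - 1L]) / (seg[i1] - seg[i1 - 1L])
    } else as.numeric(i1)
    p2 <- if (i2 < n) {
      i2 + (seg[i2] - level) / (seg[i2] - seg[i2 + 1L])
    } else as.numeric(i2)
    (p2 - p1) / rate
  }
  # decay times: interpolated time from the systolic peak to the first fall
  # below a fraction of peak amplitude (tracks the diastolic decay constant)
  decay_to <- function(frac) {
    level <- baseline + frac * amplitude
    post <- seg[pk_rel:n]
    below <- which(post < level)
    if (length(below) == 0L) return((n - pk_rel) / rate)
    i <- below[1L]
    if (i <= 1L) return(0)
    p <- i - 1 + (post[i - 1L] - level) / (post[i - 1L] - post[i])
    (p - 1) / rate
  }
  total_area <- sum(seg - baseline)
  # log-linear decay-rate estimate over the 20-80% post-peak region: a
  # noise-averaged alternative to single crossing times
  post <- seg[pk_rel:n] - baseline
  in_band <- which(post <= 0.8 * amplitude & post >= 0.2 * amplitude)
  decay_rate <- if (length(in_band) >= 3L) {
    tt <- (in_band - 1) / rate
    -stats::coef(stats::lm.fit(cbind(1, tt), log(post[in_band])))[2L]
  } else 0
  d1 <- diff(seg) * rate
  d2 <- diff(d1) * rate
  c(duration = duration,
    upstroke_time = upstroke,
    diastolic_time = diastolic,
    upstroke_fraction = upstroke / duration,
    amplitude = amplitude,
    width25 = width_at(0.25),
    width50 = width_at(0.50),
    width75 = width_at(0.75),
    area = total_area / rate,
    decay50 = decay_to(0.5),
    decay25 = decay_to(0.25),
    decay_rate = unname(decay_rate),
    diastolic_area_frac = if (total_area > 0) {
      sum(seg[pk_rel:n] - baseline) / total_area
    } else 0,
    d1_max = max(d1), d1_min = min(d1),
    d2_max = max(d2), d2_min = min(d2))
}

#' Frequency-domain features around a cycle
#'
#' Spectral descriptors computed from a window centered on the cycle and
#' extending `margin` seconds before its start and after its end (clipped at
#' record boundaries, minimum 2 s of context). The analysis band is the
#' cardiac band 0.5-4.0 Hz. Features (7): total band power; relative power
#' in 0.5-1.5, 1.5-2.5 and 2.5-4.0 Hz (summing to 1 over the band); dominant
#' frequency; spectral entropy (bits) of the band-normalized periodogram;
#' harmonic ratio (power near twice the dominant frequency over power at the
#' dominant frequency).
#'
#' @param signal The preprocessed `raw_signal` the cycle was detected in.
#' @param cycle A `cardiac_cycle`.
#' @param margin Context margin in seconds (default 5).
#' @return Named numeric vector of length 7.
#' @export
extract_frequency_features <- function(signal, cycle, margin = 5) {
  stopifnot(inherits(signal, "raw_signal"), inherits(cycle, "cardiac_cycle"))
  rate <- signal$rate
  lo <- max(1L, cycle$valley_start - round(margin * rate))
  hi <- min(length(signal$samples), cycle$valley_end + round(margin * rate))
  if ((hi - lo + 1L) / rate < 2) {
    stop("extract_frequency_features: insufficient context after clipping",
         call. = FALSE)
  }
  x <- signal$samples[lo:hi]
  x <- x - mean(x)
  n <- length(x)
  spec <- abs(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1L) / n * rate
  half <- freqs <= rate / 2
  freqs <- freqs[half]; spec <- spec[half]
  band <- freqs >= 0.5 & freqs <= 4.0
  fb <- freqs[band]; pb <- spec[band]
  total <- sum(pb)
  if (total <= 0) total <- .Machine$double.eps
  relpow <- function(a, b) sum(pb[fb >= a & fb < b]) / total
  p <- pb / total
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  dom_i <- which.max(pb)
  dom_f <- fb[dom_i]
  near <- function(f0) {
    i <- which.min(abs(fb - f0))
    sum(pb[max(1L, i - 1L):min(length(pb), i + 1L)])
  }
  harm <- if (2 * dom_f <= 4.0) near(2 * dom_f) / max(near(dom_f), .Machine$double.eps) else 0
  c(total_power = sum(pb),
    relpow_lo = relpow(0.5, 1.5),
    relpow_mid = relpow(1.5, 2.5),
    relpow_hi = sum(pb[fb >= 2.5 & fb <= 4.0]) / total,
    dominant_freq = dom_f,
    spectral_entropy = entropy,
    harmonic_ratio = harm)
}

#' Construct a tri-axial accelerometer stream
#'
#' @param t Time stamps in seconds (uniform).
#' @param x,y,z Per-axis acceleration in g.
#' @param rate Sampling rate in Hz.
#' @param subject_id Optional subject identifier.
#' @return An `accel_stream` object (data.frame-backed).
#' @export
accel_stream <- function(t, x, y, z, rate, subject_id = NA_character_) {
  stopifnot(length(t) == length(x), length(x) == length(y),
            length(y) == length(z), rate > 0)
  structure(
    list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         z = as.numeric(z), rate = as.numeric(rate),
         subject_id = subject_id),
    class = "accel_stream"
  )
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream> %d samples @ %g Hz (%.1f s), subject %s\n",
              length(x$t), x$rate, length(x$t) / x$rate, x$subject_id))
  invisible(x)
}

#' Slice an accelerometer stream by time
#' @param accel An `accel_stream`.
#' @param t0,t1 Slice bounds in seconds (inclusive).
#' @return An `accel_stream` restricted to `[t0, t1]` (may be empty).
#' @export
slice_accel <- function(accel, t0, t1) {
  keep <- accel$t >= t0 & accel$t <= t1
  structure(
    list(t = accel$t[keep], x = accel$x[keep], y = accel$y[keep],
         z = accel$z[keep], rate = accel$rate, subject_id = accel$subject_id),
    class = "accel_stream"
  )
}

#' Accelerometer context features for BP estimation
#'
#' Motion descriptors of the accelerometer slice co-temporal with a cycle's
#' frequency window (10 features): per-axis mean and SD, mean and SD of the
#' magnitude signal, motion intensity (mean absolute derivative of the
#' magnitude), and a validity flag. An empty slice yields all-zero sentinel
#' features with `accel_valid = 0`.
#'
#' @param accel An `accel_stream` slice (possibly empty or `NULL`).
#' @return Named numeric vector of length 10.
#' @export
extract_accel_features <- function(accel) {
  empty <- is.null(accel) || length(accel$t) == 0L
  if (empty) {
    return(c(ax_mean = 0, ay_mean = 0, az_mean = 0,
             ax_sd = 0, ay_sd = 0, az_sd = 0,
             mag_mean = 0, mag_sd = 0, motion_intensity = 0,
             accel_valid = 0))
  }
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  mag <- sqrt(accel$x^2 + accel$y^2 + accel$z^2)
  intensity <- if (length(mag) > 1L) mean(abs(diff(mag)) * accel$rate) else 0
  c(ax_mean = mean(accel$x), ay_mean = mean(accel$y), az_mean = mean(accel$z),
    ax_sd = sd0(accel$x), ay_sd = sd0(accel$y), az_sd = sd0(accel$z),
    mag_mean = mean(mag), mag_sd = sd0(mag),
    motion_intensity = intensity, accel_valid = 1)
}

#' All features for one cardiac cycle
#'
#' Combines temporal, frequency, accelerometer and heart-rate features into
#' the fixed, documented 35-element feature vector used by the BP models
#' (17 temporal + 7 spectral + 10 accelerometer + heart rate).
#'
#' @param signal Preprocessed `raw_signal`.
#' @param cycle A `cardiac_cycle`.
#' @param accel Optional `accel_stream` covering the session (sliced to the
#'   cycle's frequency window internally); `NULL` gives sentinel features.
#' @param margin Frequency/accelerometer context margin in seconds.
#' @return Named numeric vector of length 35.
#' @export
extract_cycle_features <- function(signal, cycle, accel = NULL, margin = 5) {
  tf <- extract_temporal_features(cycle)
  ff <- extract_frequency_features(signal, cycle, margin)
  sl <- if (is.null(accel)) NULL else {
    slice_accel(accel, cycle$start_time - margin,
                cycle$start_time + cycle$duration + margin)
  }
  af <- extract_accel_features(sl)
  c(tf, ff, af, heart_rate = 60 / cycle$duration)
}

#' Feature table for a preprocessed PPG session
#'
#' Extracts the full per-cycle feature vector for every kept cycle of a
#' [ppg_preprocess()] result and returns them as a data frame with
#' `subject_id` and `timestamp_s` columns. When `readings` is supplied, only
#' cycles within `tolerance` seconds of some reading are featurized (the
#' others could never be paired with ground truth).
#'
#' @param prep Result of [ppg_preprocess()].
#' @param accel Optional `accel_stream`.
#' @param subject_id Subject identifier stored with each row.
#' @param readings Optional `bp_readings` data frame (see
#'   [pair_with_ground_truth()]).
#' @param tolerance Pairing tolerance in seconds (default 30).
#' @param margin Context margin in seconds (default 5).
#' @param smooth_k Rolling-median span (odd cycle count) applied to the
#'   temporal and heart-rate features within contiguous runs of cycles.
#'   Blood pressure varies over minutes while cycles arrive about once per
#'   second, so averaging morphology over a few adjacent beats suppresses
#'   per-beat measurement noise (including the slow beat-to-sample-grid
#'   phase artifact of low-rate wrist sensors) without blurring the BP
#'   signal, whose attribution already assumes constancy over +-30 s.
#'   Default 21 (about 18 s at rest); 1 disables smoothing.
#' @return Data frame: `subject_id`, `timestamp_s`, then the 35 feature
#'   columns.
#' @export
ppg_session_features <- function(prep, accel = NULL, subject_id = "s1",
                                 readings = NULL, tolerance = 30, margin = 5,
                                 smooth_k = 21L) {
  cycles <- prep$cycles[prep$kept]
  if (!is.null(readings) && length(cycles) > 0L) {
    near <- vapply(cycles, function(cc) {
      any(abs(cc$start_time - readings$timestamp) <= tolerance)
    }, logical(1))
    cycles <- cycles[near]
  }
  if (length(cycles) == 0L) {
    return(data.frame(subject_id = character(), timestamp_s = numeric()))
  }
  rows <- lapply(cycles, function(cc) {
    extract_cycle_features(prep$signal, cc, accel, margin)
  })
  feat <- as.data.frame(do.call(rbind, rows))
  times <- vapply(cycles, function(cc) cc$start_time, numeric(1))
  if (smooth_k > 1L) {
    smooth_cols <- c(names(extract_temporal_features(cycles[[1L]])),
                     "heart_rate")
    # contiguous runs only: never smooth across gaps (> 5 s) between the
    # windows attributed to different readings
    run_id <- cumsum(c(1, diff(times) > 5))
    for (r in unique(run_id)) {
      idx <- which(run_id == r)
      k <- min(smooth_k, length(idx))
      if (k %% 2L == 0L) k <- k - 1L
      if (k < 3L) next
      for (cl in smooth_cols) {
        feat[[cl]][idx] <- stats::runmed(feat[[cl]][idx], k,
                                         endrule = "median")
      }
    }
  }
  cbind(data.frame(subject_id = subject_id, timestamp_s = times), feat)
}
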
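#' Detect cardiac cycles in a preprocessed PPG signal
#'
#' Cycle detection follows a first-derivative transformation: the steepest
#' systolic upslopes are located as prominent maxima of the first derivative
#' separated by a 0.25 s refractory period; the systolic peak is the signal
#' maximum after each upslope; the diastolic valley is the minimum between
#' consecutive peaks. Cycles run valley-to-valley and must satisfy a
#' physiological duration bound.
#'
#' @param signal A normalized, band-passed `raw_signal`.
#' @param min_duration,max_duration Admissible cycle duration bounds in
#'   seconds (defaults 0.25 and 2.0, i.e. 30-240 bpm).
#' @param refractory Minimum spacing between upslopes in seconds (default
#'   0.25).
#' @param slope_frac Fraction of the maximum derivative a candidate upslope
#'   must reach (default 0.3).
#' @return A list of `cardiac_cycle` objects, each with `valley_start`,
#'   `systolic_peak`, `valley_end` (sample indices into `signal`), `segment`
#'   (amplitude slice) and `duration` (seconds). May be empty.
#' @export
detect_cycles <- function(signal, min_duration = 0.25, max_duration = 2.0,
                          refractory = 0.25, slope_frac = 0.3) {
  stopifnot(inherits(signal, "raw_signal"))
  x <- signal$samples
  rate <- signal$rate
  dx <- diff(x) * rate
  if (max(dx) <= sqrt(.Machine$double.eps)) {
    return(list())
  }
  thr <- slope_frac * max(dx)
  pk <- pracma::findpeaks(dx, minpeakheight = thr,
                          minpeakdistance = max(1L, round(refractory * rate)))
  if (is.null(pk) || nrow(pk) < 2L) {
    return(list())
  }
  upslopes <- sort(pk[, 2])
  m <- length(upslopes)
  n <- length(x)
  max_span <- round(max_duration * rate)

  # systolic peak: signal maximum between each upslope and the next
  peaks <- integer(m)
  for (k in seq_len(m)) {
    to <- if (k < m) upslopes[k + 1L] else min(n, upslopes[k] + max_span)
    seg <- upslopes[k]:to
    peaks[k] <- seg[which.max(x[seg])]
  }
  peaks <- unique(peaks)
  m <- length(peaks)
  if (m < 2L) return(list())

  # diastolic valleys: minima between consecutive peaks, plus boundary
  # valleys before the first and after the last peak
  valleys <- integer(m + 1L)
  from0 <- max(1L, peaks[1L] - max_span)
  seg0 <- from0:peaks[1L]
  valleys[1L] <- seg0[which.min(x[seg0])]
  for (k in seq_len(m - 1L)) {
    seg <- peaks[k]:peaks[k + 1L]
    valleys[k + 1L] <- seg[which.min(x[seg])]
  }
  segL <- peaks[m]:min(n, peaks[m] + max_span)
  valleys[m + 1L] <- segL[which.min(x[segL])]

  # sub-sample landmark refinement (parabolic interpolation) removes the
  # sample-grid quantization of durations and upstroke times
  refine <- function(i) {
    if (i <= 1L || i >= n) return(0)
    denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
    if (abs(denom) < .Machine$double.eps) return(0)
    d <- 0.5 * (x[i - 1L] - x[i + 1L]) / denom
    max(min(d, 0.5), -0.5)
  }

  cycles <- vector("list", m)
  kept <- 0L
  for (k in seq_len(m)) {
    vs <- valleys[k]
    ve <- valleys[k + 1L]
    if (ve <= vs + 1L) next
    seg <- vs:ve
    sp <- seg[which.max(x[seg])]
    if (!(vs < sp && sp < ve)) next
    t0 <- signal$start_time
    ts_start <- t0 + (vs - 1L + refine(vs)) / rate
    ts_peak <- t0 + (sp - 1L + refine(sp)) / rate
    ts_end <- t0 + (ve - 1L + refine(ve)) / rate
    dur <- ts_end - ts_start
    if (dur < min_duration || dur > max_duration) next
    kept <- kept + 1L
    cycles[[kept]] <- structure(
      list(valley_start = vs, systolic_peak = sp, valley_end = ve,
           segment = x[vs:ve], duration = dur, rate = rate,
           start_time = ts_start, t_peak = ts_peak, t_end = ts_end),
      class = "cardiac_cycle"
    )
  }
  cycles[seq_len(kept)]
}

#' @export
print.cardiac_cycle <- function(x, ...) {
  cat(sprintf("<cardiac_cycle> t=%.2f s, duration %.3f s, peak idx %d\n",
              x$start_time, x$duration, x$systolic_peak - x$valley_start + 1L))
  invisible(x)
}

#' Resample a cycle's waveform to a fixed length
#'
#' Linear interpolation of the valley-to-valley segment onto `length_out`
#' evenly spaced points, so cycles of different durations become comparable.
#'
#' @param cycle A `cardiac_cycle` (or a bare numeric segment).
#' @param length_out Target number of points (default 64).
#' @return Numeric vector of length `length_out`.
#' @export
resample_cycle <- function(cycle, length_out = 64L) {
  seg <- if (inherits(cycle, "cardiac_cycle")) cycle$segment else as.numeric(cycle)
  if (length(seg) < 2L) stop("resample_cycle: segment too short", call. = FALSE)
  stats::approx(x = seq(0, 1, length.out = length(seg)), y = seg,
                xout = seq(0, 1, length.out = length_out))$y
}

#' Build sliding-window cycle templates
#'
#' The detected cycle sequence is traversed with a non-overlapping sliding
#' window; within each window every cycle is resampled to a fixed length and
#' a template waveform is computed as the pointwise location statistic of the
#' window members. The pointwise median is the default: it tolerates the
#' artifact-corrupted cycles (noise bursts, inversions) the screening step is
#' meant to catch, which would otherwise contaminate the template itself.
#'
#' @param cycles List of `cardiac_cycle` objects.
#' @param window_size Number of consecutive cycles per window (default 10).
#' @param template_length Resampled template length L (default 64).
#' @param statistic `"median"` (default, robust) or `"mean"`.
#' @return List of `cycle_template` objects with `waveform` (length L),
#'   `window_span` (first/last cycle index), `n_cycles` and `median_duration`
#'   (seconds, used for the duration-deviation quality metric). Empty input
#'   gives an empty list; a trailing partial window still yields a template.
#' @export
build_templates <- function(cycles, window_size = 10L, template_length = 64L,
                            statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (window_size < 1L) stop("build_templates: window_size must be >= 1", call. = FALSE)
  n <- length(cycles)
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = window_size)
  lapply(starts, function(s) {
    idx <- s:min(n, s + window_size - 1L)
    mat <- vapply(cycles[idx], resample_cycle, numeric(template_length),
                  length_out = template_length)
    wf <- if (statistic == "median") {
      apply(mat, 1L, stats::median)
    } else {
      rowMeans(mat)
    }
    structure(
      list(waveform = wf, window_span = c(idx[1L], idx[length(idx)]),
           n_cycles = length(idx),
           median_duration = stats::median(
             vapply(cycles[idx], function(cc) cc$duration, numeric(1)))),
      class = "cycle_template"
    )
  })
}

zscore <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s <= 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Score one cycle against its window template
#'
#' Compares the resampled cycle with the template on three metrics: Pearson
#' correlation of the waveforms, normalized Euclidean distance between the
#' z-scored waveforms (amplitude-invariant shape distance, equal to
#' sqrt(2 (1 - r))), and the relative deviation of the cycle duration from
#' the window's median duration. The keep verdict is the conjunction of the
#' three configurable thresholds.
#'
#' @param cycle A `cardiac_cycle`.
#' @param template A `cycle_template`.
#' @param thresholds Named list with `correlation` (keep if >=, default 0.9),
#'   `norm_distance` (keep if <=, default 0.5) and `duration_deviation`
#'   (keep if <=, default 0.25).
#' @return A `quality_report` list: `correlation`, `norm_distance`,
#'   `duration_deviation`, `keep`.
#' @export
score_cycle_quality <- function(cycle, template,
                                thresholds = list(correlation = 0.9,
                                                  norm_distance = 0.5,
                                                  duration_deviation = 0.25)) {
  stopifnot(inherits(template, "cycle_template"))
  L <- length(template$waveform)
  cw <- resample_cycle(cycle, length_out = L)
  if (length(cw) != L) {
    stop("score_cycle_quality: template length mismatch", call. = FALSE)
  }
  zc <- zscore(cw)
  zt <- zscore(template$waveform)
  r <- if (all(zc == 0) || all(zt == 0)) 0 else mean(zc * zt)
  nd <- sqrt(mean((zc - zt)^2))
  dd <- abs(cycle$duration - template$median_duration) / template$median_duration
  structure(
    list(correlation = r, norm_distance = nd, duration_deviation = dd,
         keep = (r >= thresholds$correlation) &&
                (nd <= thresholds$norm_distance) &&
                (dd <= thresholds$duration_deviation)),
    class = "quality_report"
  )
}

#' Full PPG preprocessing chain: normalize, despike, band-pass, detect, screen
#'
#' Runs the complete signal-quality pipeline on a raw PPG stream and returns
#' the detected cycles together with per-cycle quality reports.
#'
#' @param signal A `raw_signal` PPG stream.
#' @param config Named list overriding any of: `hampel_half_window`,
#'   `hampel_n_sigmas`, `band_low`, `band_high`, `band_order`,
#'   `window_size`, `template_length`, `template_statistic`, `thresholds`
#'   (see [score_cycle_quality()]).
#' @return List with `cycles` (all detected), `reports` (one
#'   `quality_report` per cycle), `kept` (logical vector), `templates`, and
#'   `signal` (the preprocessed `raw_signal`).
#' @export
ppg_preprocess <- function(signal, config = list()) {
  cfg <- utils::modifyList(
    list(hampel_half_window = 5L, hampel_n_sigmas = 3,
         band_low = 0.5, band_high = 4.0, band_order = 4L,
         window_size = 10L, template_length = 64L,
         template_statistic = "median",
         thresholds = list(correlation = 0.9, norm_distance = 0.5,
                           duration_deviation = 0.25)),
    config)
  s <- normalize_signal(signal)
  s <- hampel_filter(s, cfg$hampel_half_window, cfg$hampel_n_sigmas)
  s <- bandpass_filter(s, cfg$band_low, cfg$band_high, cfg$band_order)
  cycles <- detect_cycles(s)
  templates <- build_templates(cycles, cfg$window_size, cfg$template_length,
                               cfg$template_statistic)
  reports <- vector("list", length(cycles))
  if (length(cycles) > 0L) {
    tidx <- (seq_along(cycles) - 1L) %/% cfg$window_size + 1L
    for (i in seq_along(cycles)) {
      reports[[i]] <- score_cycle_quality(cycles[[i]], templates[[tidx[i]]],
                                          cfg$thresholds)
    }
  }
  list(cycles = cycles, reports = reports,
       kept = vapply(reports, function(r) r$keep, logical(1)),
       templates = templates, signal = s)
}

#' Screen an explicit list of cycles (template quality control only)
#'
#' Convenience wrapper used when cycles are already segmented (e.g. from the
#' synthetic generator): builds templates and scores every cycle.
#'
#' @inheritParams ppg_preprocess
#' @param cycles List of `cardiac_cycle` objects.
#' @return Same structure as [ppg_preprocess()] minus `signal`.
#' @export
screen_cycles <- function(cycles, config = list()) {
  cfg <- utils::modifyList(
    list(window_size = 10L, template_length = 64L,
         template_statistic = "median",
         thresholds = list(correlation = 0.9, norm_distance = 0.5,
                           duration_deviation = 0.25)),
    config)
  templates <- build_templates(cycles, cfg$window_size, cfg$template_length,
                               cfg$template_statistic)
  reports <- vector("list", length(cycles))
  if (length(cycles) > 0L) {
    tidx <- (seq_along(cycles) - 1L) %/% cfg$window_size + 1L
    for (i in seq_along(cycles)) {
      reports[[i]] <- score_cycle_quality(cycles[[i]], templates[[tidx[i]]],
                                          cfg$thresholds)
    }
  }
  list(cycles = cycles, reports = reports,
       kept = vapply(reports, function(r) r$keep, logical(1)),
       templates = templates)
}
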
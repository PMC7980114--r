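#' Two-lobe PPG pulse waveform on a normalized phase axis
#'
#' Documented morphology-to-BP mapping used by the generator (an invented
#' statistical stand-in for vascular physiology, not a validated
#' hemodynamic model): the pulse rises as a sine quarter-wave from the
#' diastolic valley to the systolic peak over a phase fraction `u`, then
#' decays exponentially back to the valley with a dicrotic bump. The
#' upstroke fraction decreases affinely with SBP and the decay constant
#' decreases affinely with DBP:
#' `u = 0.42 - 0.002 (SBP - 120)` (clamped to \[0.10, 0.48\]),
#' `tau = 0.45 - 0.004 (DBP - 80)` (clamped to \[0.12, 0.80\]).
#'
#' @param phase Phase in \[0, 1).
#' @param sbp,dbp Per-beat blood pressures in mm Hg.
#' @return Pulse amplitude (0 at the valleys, 1 at the systolic peak).
#' @export
ppg_pulse_shape <- function(phase, sbp, dbp) {
  sbp <- rep_len(sbp, length(phase))
  dbp <- rep_len(dbp, length(phase))
  u <- pmin(pmax(0.42 - 0.002 * (sbp - 120), 0.10), 0.48)
  tau <- pmin(pmax(0.45 - 0.004 * (dbp - 80), 0.12), 0.80)
  rising <- phase < u
  out <- numeric(length(phase))
  out[rising] <- sin(pi / 2 * phase[rising] / u[rising])
  ph <- phase[!rising]
  uu <- u[!rising]; tt <- tau[!rising]
  base <- exp(-(1 - uu) / tt)
  decay <- (exp(-(ph - uu) / tt) - base) / (1 - base)
  dicrotic <- 0.12 * exp(-((ph - uu - 0.25) / 0.07)^2) * (1 - ph)
  out[!rising] <- decay + dicrotic
  out
}

#' Upstroke fraction implied by an SBP value (generator mapping)
#' @param sbp SBP in mm Hg.
#' @return Phase fraction of the systolic upstroke.
#' @export
upstroke_fraction_for_sbp <- function(sbp) {
  pmin(pmax(0.42 - 0.002 * (sbp - 120), 0.10), 0.48)
}

piecewise_value <- function(t, duration, values) {
  # values at evenly spaced knots over [0, duration], linear in between
  if (length(values) == 1L) return(rep(values, length(t)))
  knots <- seq(0, duration, length.out = length(values))
  stats::approx(knots, values, xout = pmin(pmax(t, 0), duration))$y
}

#' Generate a synthetic PPG monitoring session with ground truth
#'
#' Emits a PPG stream whose per-cycle morphology follows the documented
#' [ppg_pulse_shape()] mapping of the underlying SBP/DBP trajectories,
#' plus Gaussian sensor noise and artifact-corrupted cycles (noise bursts
#' and inversions), a co-temporal accelerometer stream (wrist at rest),
#' cuff BP readings every 30 simulated minutes, and complete ground truth.
#'
#' @param duration Session length in seconds.
#' @param hr Heart-rate profile in bpm: scalar or vector of knot values
#'   interpolated piecewise-linearly over the session (40-180).
#' @param sbp,dbp BP trajectories in mm Hg, same knot convention
#'   (30 < dbp < sbp < 300).
#' @param noise_sd Gaussian noise SD relative to the unit pulse amplitude
#'   (default 0.05).
#' @param artifact_rate Corrupted cycles per minute (default 0).
#' @param rate Sampling rate in Hz (default 64).
#' @param hr_jitter Per-beat fractional period jitter SD (default 0).
#' @param reading_interval Cuff-reading cadence in seconds (default 1800).
#' @param seed Integer seed (mandatory).
#' @param subject_id Subject identifier.
#' @return List with `ppg` (`raw_signal`), `accel` (`accel_stream`),
#'   `readings` (`bp_readings`), and `truth` (list: `beat_times`,
#'   `beat_sbp`, `beat_dbp`, `beat_corrupted`, `n_beats`).
#' @export
gen_ppg_session <- function(duration, hr = 70, sbp = 120, dbp = 80,
                            noise_sd = 0.05, artifact_rate = 0, rate = 64,
                            hr_jitter = 0, reading_interval = 1800,
                            seed, subject_id = "s1") {
  if (missing(seed)) stop("gen_ppg_session: seed is mandatory", call. = FALSE)
  if (any(hr < 40 | hr > 180)) {
    stop("gen_ppg_session: heart rate must be within 40-180 bpm", call. = FALSE)
  }
  if (any(!(30 < dbp & dbp < sbp & sbp < 300))) {
    stop("gen_ppg_session: need 30 < dbp < sbp < 300", call. = FALSE)
  }
  set.seed(seed)
  # beat schedule
  beat_times <- numeric(0)
  t <- 0
  while (t < duration) {
    beat_times <- c(beat_times, t)
    hr_t <- piecewise_value(t, duration, hr)
    period <- 60 / hr_t
    if (hr_jitter > 0) period <- period * (1 + stats::rnorm(1, 0, hr_jitter))
    t <- t + max(period, 60 / 200)
  }
  nb <- length(beat_times)
  beat_sbp <- piecewise_value(beat_times, duration, sbp)
  beat_dbp <- piecewise_value(beat_times, duration, dbp)

  n <- round(duration * rate)
  ts <- (seq_len(n) - 1L) / rate
  x <- numeric(n)
  bounds <- c(beat_times, duration)
  beat_of <- findInterval(ts, bounds, rightmost.closed = TRUE)
  beat_of[beat_of < 1L] <- 1L
  beat_of[beat_of > nb] <- nb
  period_of <- bounds[beat_of + 1L] - bounds[beat_of]
  phase <- (ts - bounds[beat_of]) / period_of
  phase <- pmin(pmax(phase, 0), 1 - 1e-9)
  x <- ppg_pulse_shape(phase, beat_sbp[beat_of], beat_dbp[beat_of])
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)

  corrupted <- logical(nb)
  n_art <- stats::rpois(1, artifact_rate * duration / 60)
  if (n_art > 0) {
    which_beats <- sample.int(nb, min(n_art, nb))
    for (b in which_beats) {
      corrupted[b] <- TRUE
      idx <- which(beat_of == b)
      if (stats::runif(1) < 0.5) {
        x[idx] <- x[idx] + stats::rnorm(length(idx), 0, 0.5) # noise burst
      } else {
        x[idx] <- -x[idx] + 2 * mean(x[idx]) # inversion about the local mean
      }
    }
  }

  accel <- accel_stream(t = ts,
                        x = stats::rnorm(n, 0, 0.01),
                        y = stats::rnorm(n, 0, 0.01),
                        z = 1 + stats::rnorm(n, 0, 0.01),
                        rate = rate, subject_id = subject_id)

  rt <- if (reading_interval <= duration) {
    seq(reading_interval, duration, by = reading_interval)
  } else {
    duration / 2
  }
  readings <- bp_readings(timestamp = rt,
                          sbp = piecewise_value(rt, duration, sbp),
                          dbp = piecewise_value(rt, duration, dbp),
                          subject_id = subject_id)

  list(ppg = raw_signal(x, rate, 0), accel = accel, readings = readings,
       truth = list(beat_times = beat_times, beat_sbp = beat_sbp,
                    beat_dbp = beat_dbp, beat_corrupted = corrupted,
                    n_beats = nb))
}

#' Generate standalone synthetic cardiac cycles for screening tests
#'
#' Emits a sequence of `cardiac_cycle` objects drawn from the documented
#' pulse shape with small measurement noise and duration jitter, of which a
#' chosen fraction is corrupted (half heavy noise bursts, half sign
#' inversions). Used to exercise the template quality screen with known
#' corruption ground truth.
#'
#' @param n Number of cycles.
#' @param corrupt_frac Fraction corrupted (default 0.25).
#' @param rate Sampling rate in Hz (default 64).
#' @param hr Heart rate in bpm (default 70).
#' @param noise_sd Clean measurement noise SD (default 0.05).
#' @param burst_sd Artifact noise-burst SD (default 0.5).
#' @param seed Integer seed.
#' @return List with `cycles` and logical `corrupted`.
#' @export
gen_cycle_set <- function(n, corrupt_frac = 0.25, rate = 64, hr = 70,
                          noise_sd = 0.05, burst_sd = 0.5, seed) {
  if (missing(seed)) stop("gen_cycle_set: seed is mandatory", call. = FALSE)
  set.seed(seed)
  period <- 60 / hr
  corrupted <- rep(FALSE, n)
  corrupted[sample.int(n, round(corrupt_frac * n))] <- TRUE
  inverted <- corrupted & (stats::runif(n) < 0.5)
  cycles <- vector("list", n)
  t0 <- 0
  for (i in seq_len(n)) {
    dur <- period * stats::rnorm(1, 1, 0.02)
    m <- round(dur * rate)
    ph <- (seq_len(m) - 1L) / m
    seg <- ppg_pulse_shape(ph, 120, 80) + stats::rnorm(m, 0, noise_sd)
    if (corrupted[i]) {
      if (inverted[i]) seg <- -seg else seg <- seg + stats::rnorm(m, 0, burst_sd)
    }
    cycles[[i]] <- structure(
      list(valley_start = 1L, systolic_peak = which.max(seg),
           valley_end = m, segment = seg, duration = m / rate,
           rate = rate, start_time = t0),
      class = "cardiac_cycle"
    )
    t0 <- t0 + m / rate
  }
  list(cycles = cycles, corrupted = corrupted)
}

#' Generate a scripted synthetic accelerometer session
#'
#' Per-class generative regimes (documented; amplitudes in g): rest and
#' standing are gravity plus small noise at different wrist orientations;
#' walking is a 2 Hz arm-swing sinusoid (amplitude 0.25), nordic walking
#' 2 Hz at 0.4 with a stronger second axis, running 3 Hz at 0.8, exercise
#' 1 Hz at 0.5 on two axes; eating is intermittent 0.5 Hz wrist rotations
#' (gravity tilting) with pauses; washing is 2.5 Hz at 0.15; chores are
#' broadband noise bursts (SD 0.3, 50% duty); hand activities are small
#' broadband noise (SD 0.03). A per-subject amplitude/frequency factor
#' (lognormal, ~10%) individualizes subjects.
#'
#' @param script List of `(label, duration_s)` pairs, e.g.
#'   `list(c("rest", 10), c("walking", 20))`; labels from
#'   [activity_labels()].
#' @param rate Sampling rate in Hz (default 50).
#' @param seed Integer seed.
#' @param subject_id Subject identifier.
#' @return An `accel_stream` with an extra `labels` element (per-sample
#'   ground-truth labels).
#' @export
gen_activity_session <- function(script, rate = 50, seed, subject_id = "s1") {
  if (missing(seed)) stop("gen_activity_session: seed is mandatory", call. = FALSE)
  set.seed(seed)
  amp_f <- exp(stats::rnorm(1, 0, 0.1))
  freq_f <- exp(stats::rnorm(1, 0, 0.05))
  xs <- ys <- zs <- labs <- list()
  t_off <- 0
  for (entry in script) {
    lab <- as.character(entry[[1L]])
    dur <- as.numeric(entry[[2L]])
    if (!(lab %in% activity_labels())) {
      stop("gen_activity_session: unknown label '", lab, "'", call. = FALSE)
    }
    n <- round(dur * rate)
    t <- (seq_len(n) - 1L) / rate
    g <- c(0, 0, 1)
    ax <- ay <- az <- numeric(n)
    noise <- 0.01
    if (lab == "rest") {
      noise <- 0.008
    } else if (lab == "standing") {
      g <- c(0.35, 0.1, 0.93); noise <- 0.012
    } else if (lab == "walking") {
      f <- 2 * freq_f
      ax <- 0.25 * amp_f * sin(2 * pi * f * t)
      ay <- 0.10 * amp_f * sin(2 * pi * 2 * f * t + 0.7)
      noise <- 0.02
    } else if (lab == "nordic_walking") {
      f <- 2 * freq_f
      ax <- 0.40 * amp_f * sin(2 * pi * f * t)
      ay <- 0.25 * amp_f * sin(2 * pi * f * t + 1.2)
      noise <- 0.03
    } else if (lab == "running") {
      f <- 3 * freq_f
      ax <- 0.80 * amp_f * sin(2 * pi * f * t)
      az <- 0.40 * amp_f * sin(2 * pi * f * t + 0.5)
      noise <- 0.06
    } else if (lab == "exercise") {
      f <- 1 * freq_f
      ax <- 0.50 * amp_f * sin(2 * pi * f * t)
      ay <- 0.50 * amp_f * sin(2 * pi * f * t + pi / 2)
      noise <- 0.04
    } else if (lab == "eating") {
      f <- 0.5 * freq_f
      gate <- as.numeric(sin(2 * pi * 0.1 * t) > 0) # intermittent gestures
      tilt <- 1.0 * amp_f * sin(2 * pi * f * t) * gate
      g <- c(0, 0, 1)
      ax <- sin(tilt) * 0.3
      az <- (cos(tilt) - 1) * 0.3
      noise <- 0.015
    } else if (lab == "washing") {
      f <- 2.5 * freq_f
      ax <- 0.15 * amp_f * sin(2 * pi * f * t)
      ay <- 0.15 * amp_f * sin(2 * pi * f * t + 0.9)
      noise <- 0.03
    } else if (lab == "chores") {
      gate <- stats::rbinom(n, 1, 0.5)
      gate <- lowpass_axis(gate, rate, 1) > 0.5
      ax <- stats::rnorm(n, 0, 0.3) * gate
      ay <- stats::rnorm(n, 0, 0.3) * gate
      az <- stats::rnorm(n, 0, 0.2) * gate
      noise <- 0.02
    } else if (lab == "hand_activities") {
      ax <- stats::rnorm(n, 0, 0.03)
      ay <- stats::rnorm(n, 0, 0.03)
      noise <- 0.01
    }
    xs[[length(xs) + 1L]] <- g[1L] + ax + stats::rnorm(n, 0, noise)
    ys[[length(ys) + 1L]] <- g[2L] + ay + stats::rnorm(n, 0, noise)
    zs[[length(zs) + 1L]] <- g[3L] + az + stats::rnorm(n, 0, noise)
    labs[[length(labs) + 1L]] <- rep(lab, n)
    t_off <- t_off + dur
  }
  x <- unlist(xs); y <- unlist(ys); z <- unlist(zs)
  out <- accel_stream(t = (seq_along(x) - 1L) / rate, x = x, y = y, z = z,
                      rate = rate, subject_id = subject_id)
  out$labels <- unlist(labs)
  out
}

#' Generate a synthetic well-being record table
#'
#' Draws the feature schema (heart_rate bpm, sbp/dbp mm Hg, weight kg,
#' temperature deg C, humidity %RH) from documented Gaussian marginals with
#' configurable pairwise correlations, labels each record by a declarative
#' ground-truth rule, and flips labels with a given probability.
#'
#' @param n Number of records.
#' @param rule Either a one-argument function of the record data frame
#'   returning a logical "good" vector, or a character expression over the
#'   feature names (e.g. `"temperature <= 26 & humidity <= 65"`).
#' @param noise Label-flip probability in \[0, 0.5).
#' @param cor_pairs Optional list of `c(feature_a, feature_b, r)` triples
#'   imposed on the Gaussian copula (default: humidity-temperature 0.0).
#' @param seed Integer seed.
#' @return List with `records` (features + `label`) and `truth`
#'   (`rule_text`, `clean_label`, `flipped`).
#' @export
gen_wellbeing_dataset <- function(n, rule = "temperature <= 26 & humidity <= 65",
                                  noise = 0, cor_pairs = NULL, seed) {
  if (missing(seed)) stop("gen_wellbeing_dataset: seed is mandatory", call. = FALSE)
  if (!(noise >= 0 && noise < 0.5)) {
    stop("gen_wellbeing_dataset: noise must be in [0, 0.5)", call. = FALSE)
  }
  set.seed(seed)
  feats <- c("heart_rate", "sbp", "dbp", "weight", "temperature", "humidity")
  mus <- c(heart_rate = 72, sbp = 125, dbp = 80, weight = 80,
           temperature = 24, humidity = 55)
  sds <- c(heart_rate = 10, sbp = 15, dbp = 10, weight = 12,
           temperature = 4, humidity = 12)
  R <- diag(length(feats))
  dimnames(R) <- list(feats, feats)
  for (cp in cor_pairs) {
    a <- as.character(cp[[1L]]); b <- as.character(cp[[2L]])
    r <- as.numeric(cp[[3L]])
    if (!(a %in% feats && b %in% feats)) {
      stop("gen_wellbeing_dataset: unknown feature in cor_pairs", call. = FALSE)
    }
    R[a, b] <- R[b, a] <- r
  }
  z <- MASS::mvrnorm(n, mu = rep(0, length(feats)), Sigma = R)
  df <- as.data.frame(sweep(sweep(z, 2L, sds, "*"), 2L, mus, "+"))
  names(df) <- feats
  df$humidity <- pmin(pmax(df$humidity, 0), 100)
  good <- if (is.function(rule)) {
    rule(df)
  } else {
    ok <- all(all.vars(str2lang(rule)) %in% feats)
    if (!ok) stop("gen_wellbeing_dataset: rule references unknown feature",
                  call. = FALSE)
    eval(str2lang(rule), envir = df)
  }
  clean <- ifelse(good, "good", "bad")
  flipped <- stats::runif(n) < noise
  lab <- ifelse(flipped, ifelse(clean == "good", "bad", "good"), clean)
  records <- df
  records$label <- lab
  list(records = records,
       truth = list(rule_text = if (is.function(rule)) "<function>" else rule,
                    clean_label = clean, flipped = flipped))
}

#' Generate a synthetic psychophysiological profile dataset
#'
#' One row per subject with speech-summary and cardiac features drawn from
#' documented per-class Gaussian shifts (motivated: baseline pitch
#' variability and energy, low heart rate, high RMSSD; anxious: higher
#' heart rate and pitch, low RMSSD; depressed: lower pitch variability and
#' energy, reduced pitch) and a beat-to-beat interval series consistent
#' with each subject's RMSSD target (i.i.d. interval deviations of SD
#' target/sqrt(2)).
#'
#' @param n_per_class Subjects per profile class (> 0).
#' @param shifts Optional named list overriding per-class mean shifts
#'   applied to the feature block; `shift_scale = 0` collapses all classes
#'   onto the same distribution.
#' @param shift_scale Multiplier on the class separations (default 1).
#' @param n_beats Interval-series length per subject (default 120).
#' @param seed Integer seed.
#' @return List with `features` (data frame: `subject_id`, feature columns,
#'   `label`) and `intervals` (named list of per-subject interval series in
#'   ms).
#' @export
gen_profile_dataset <- function(n_per_class, shifts = NULL, shift_scale = 1,
                                n_beats = 120L, seed) {
  if (missing(seed)) stop("gen_profile_dataset: seed is mandatory", call. = FALSE)
  if (n_per_class <= 0) stop("gen_profile_dataset: n_per_class must be > 0",
                             call. = FALSE)
  set.seed(seed)
  base <- list(
    motivated = c(pitch_mean = 175, pitch_sd = 28, energy_mean = -24,
                  energy_sd = 5.5, mfcc1_mean = 0, hr = 70, rmssd = 42),
    anxious = c(pitch_mean = 195, pitch_sd = 32, energy_mean = -23,
                energy_sd = 6.5, mfcc1_mean = 1.0, hr = 86, rmssd = 20),
    depressed = c(pitch_mean = 160, pitch_sd = 16, energy_mean = -28,
                  energy_sd = 3.5, mfcc1_mean = -1.0, hr = 72, rmssd = 34))
  if (!is.null(shifts)) base <- utils::modifyList(base, shifts)
  pooled <- Reduce(`+`, base) / 3
  spread <- c(pitch_mean = 8, pitch_sd = 4, energy_mean = 1.5, energy_sd = 1,
              mfcc1_mean = 0.5, hr = 4, rmssd = 5)
  rows <- list()
  intervals <- list()
  sid <- 0L
  for (cls in psych_profiles()) {
    mu <- pooled + (base[[cls]] - pooled) * shift_scale
    for (k in seq_len(n_per_class)) {
      sid <- sid + 1L
      v <- stats::rnorm(length(mu), mu, spread)
      names(v) <- names(mu)
      v["rmssd"] <- max(v["rmssd"], 5)
      v["hr"] <- min(max(v["hr"], 45), 150)
      iv <- 60000 / v["hr"] + stats::rnorm(n_beats, 0, v["rmssd"] / sqrt(2))
      iv <- pmin(pmax(iv, 300), 2300)
      id <- sprintf("p%02d", sid)
      intervals[[id]] <- as.numeric(iv)
      v["rmssd"] <- compute_rmssd(iv)
      v["hr"] <- 60000 / mean(iv)
      rows[[id]] <- data.frame(subject_id = id, t(v), label = cls)
    }
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  list(features = features, intervals = intervals)
}
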
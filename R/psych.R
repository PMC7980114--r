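#' Construct a mono speech segment
#'
#' @param samples Numeric vector of audio amplitudes.
#' @param rate Sampling rate in Hz.
#' @return A `speech_segment` object.
#' @export
speech_segment <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop("speech_segment: samples must be finite", call. = FALSE)
  }
  if (length(samples) / rate < 1) {
    stop("speech_segment: duration must be >= 1 s", call. = FALSE)
  }
  structure(list(samples = samples, rate = as.numeric(rate),
                 duration = length(samples) / rate),
            class = "speech_segment")
}

#' @export
print.speech_segment <- function(x, ...) {
  cat(sprintf("<speech_segment> %.2f s @ %g Hz\n", x$duration, x$rate))
  invisible(x)
}

#' Normalize a speech segment's acoustic level
#'
#' Removes the DC offset and normalizes the root-mean-square level to a
#' fixed reference, so that recordings made at different volumes yield
#' identical downstream features.
#'
#' @param segment A `speech_segment`.
#' @param ref_rms Target RMS level (default 0.1).
#' @return Normalized `speech_segment`.
#' @export
preprocess_audio <- function(segment, ref_rms = 0.1) {
  stopifnot(inherits(segment, "speech_segment"))
  x <- segment$samples - mean(segment$samples)
  rms <- sqrt(mean(x^2))
  if (rms <= 1e-12) {
    stop("preprocess_audio: degenerate (silent) audio", call. = FALSE)
  }
  speech_segment(x / rms * ref_rms, segment$rate)
}

frame_signal <- function(x, rate, frame_s = 0.025, hop_s = 0.010) {
  flen <- round(frame_s * rate)
  hop <- round(hop_s * rate)
  starts <- seq(1L, length(x) - flen + 1L, by = hop)
  list(starts = starts, flen = flen)
}

pitch_autocorr <- function(frame, rate, fmin = 50, fmax = 500,
                           voicing_threshold = 0.3) {
  frame <- frame - mean(frame)
  e0 <- sum(frame^2)
  if (e0 <= 0) return(NA_real_)
  lag_min <- max(2L, floor(rate / fmax))
  lag_max <- min(length(frame) - 1L, ceiling(rate / fmin))
  if (lag_max <= lag_min) return(NA_real_)
  n <- length(frame)
  ac <- vapply(lag_min:lag_max, function(l) {
    sum(frame[1:(n - l)] * frame[(l + 1):n]) / e0
  }, numeric(1))
  i <- which.max(ac)
  if (ac[i] < voicing_threshold) return(NA_real_)
  lag <- lag_min + i - 1L
  # parabolic interpolation around the autocorrelation peak
  if (i > 1L && i < length(ac)) {
    d <- (ac[i - 1L] - ac[i + 1L]) / (2 * (ac[i - 1L] - 2 * ac[i] + ac[i + 1L]))
    if (is.finite(d) && abs(d) < 1) lag <- lag + d
  }
  rate / lag
}

mel_filterbank <- function(n_filters, n_fft, rate) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(0), mel(rate / 2), length.out = n_filters + 2L))
  bins <- floor((n_fft + 1L) * pts / rate) + 1L
  fb <- matrix(0, n_filters, n_fft %/% 2L + 1L)
  for (m in seq_len(n_filters)) {
    a <- bins[m]; b <- bins[m + 1L]; c <- bins[m + 2L]
    if (b > a) fb[m, a:b] <- (seq(a, b) - a) / (b - a)
    if (c > b) fb[m, b:c] <- (c - seq(b, c)) / (c - b)
  }
  fb
}

#' Prosodic and spectral speech features
#'
#' Computes the three base features of the speech front-end on 25 ms frames
#' with 10 ms hop: fundamental frequency (autocorrelation pitch, 50-500 Hz
#' search band, voicing threshold 0.3, unvoiced frames excluded), 13
#' mel-frequency cepstral coefficients, and smoothed log energy (5-frame
#' moving average). For each base feature the mean, SD, range, maximum and
#' minimum over frames are returned: (1 + 13 + 1) x 5 = 75 features.
#'
#' @param segment A preprocessed `speech_segment`.
#' @param n_mfcc Number of cepstral coefficients (default 13).
#' @param n_filters Mel filters (default 26).
#' @return Named numeric vector of length `(n_mfcc + 2) * 5`. Pitch
#'   statistics are `NA` (with attribute `pitch_missing = TRUE`) when no
#'   frame is voiced.
#' @export
extract_speech_features <- function(segment, n_mfcc = 13L, n_filters = 26L) {
  stopifnot(inherits(segment, "speech_segment"))
  x <- segment$samples
  rate <- segment$rate
  fr <- frame_signal(x, rate)
  flen <- fr$flen
  n_fft <- 2^ceiling(log2(flen))
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, flen - 1L) / (flen - 1L)) # Hamming
  fb <- mel_filterbank(n_filters, n_fft, rate)
  n_frames <- length(fr$starts)
  pitch <- numeric(n_frames)
  energy <- numeric(n_frames)
  mfcc <- matrix(0, n_frames, n_mfcc)
  dct_mat <- outer(seq_len(n_mfcc) - 1L, seq_len(n_filters) - 0.5,
                   function(k, m) cos(pi * k * m / n_filters))
  for (j in seq_len(n_frames)) {
    frame <- x[fr$starts[j]:(fr$starts[j] + flen - 1L)]
    pitch[j] <- pitch_autocorr(frame, rate)
    energy[j] <- 10 * log10(mean(frame^2) + 1e-12)
    fw <- frame * win
    spec <- abs(stats::fft(c(fw, rep(0, n_fft - flen))))^2
    spec <- spec[seq_len(n_fft %/% 2L + 1L)]
    melE <- log(as.numeric(fb %*% spec) + 1e-12)
    mfcc[j, ] <- as.numeric(dct_mat %*% melE)
  }
  energy <- stats::filter(energy, rep(1 / 5, 5), sides = 2)
  energy <- as.numeric(energy[!is.na(energy)])
  five <- function(v, nm) {
    if (length(v) == 0L || all(is.na(v))) {
      out <- rep(NA_real_, 5L)
    } else {
      v <- v[!is.na(v)]
      out <- c(mean(v), if (length(v) > 1L) stats::sd(v) else 0,
               max(v) - min(v), max(v), min(v))
    }
    names(out) <- paste0(nm, "_", c("mean", "sd", "range", "max", "min"))
    out
  }
  out <- c(five(pitch[!is.na(pitch)], "pitch"),
           unlist(lapply(seq_len(n_mfcc), function(k) {
             five(mfcc[, k], paste0("mfcc", k))
           })),
           five(energy, "energy"))
  attr(out, "pitch_missing") <- all(is.na(pitch))
  out
}

#' Root mean square of successive differences (RMSSD)
#'
#' Short-term heart-rate-variability measure over a beat-to-beat interval
#' series: the square root of the mean squared difference between successive
#' intervals. Intervals outside the physiological range 250-2400 ms are
#' rejected with a warning before the computation.
#'
#' @param intervals Beat-to-beat intervals in milliseconds (>= 2 valid).
#' @return RMSSD in milliseconds.
#' @export
compute_rmssd <- function(intervals) {
  intervals <- as.numeric(intervals)
  bad <- intervals < 250 | intervals > 2400
  if (any(bad)) {
    warning(sprintf("compute_rmssd: rejected %d out-of-range interval(s)",
                    sum(bad)))
    intervals <- intervals[!bad]
  }
  if (length(intervals) < 2L) {
    stop("compute_rmssd: need at least 2 valid intervals", call. = FALSE)
  }
  d <- diff(intervals)
  sqrt(mean(d^2))
}

#' The closed set of psychological profiles
#' @return Character vector of the 3 profile labels.
#' @export
psych_profiles <- function() c("motivated", "anxious", "depressed")

#' Train the psychological-profile classifier
#'
#' Fits a 3-class model (motivated / anxious / depressed) on early-fused
#' speech and cardiac features. All three classes must be present.
#'
#' @param features Data frame of numeric features plus a `label` column.
#' @param algorithm One of `"svm"` (default), `"naive_bayes"`, `"mlp"`,
#'   `"random_forest"`.
#' @param seed Integer seed.
#' @return A `profile_model` object.
#' @export
train_profile_model <- function(features, algorithm = "svm", seed = 1L) {
  algorithm <- match.arg(algorithm, c("svm", "naive_bayes", "mlp",
                                      "random_forest"))
  labs <- factor(features$label, levels = psych_profiles())
  if (length(unique(features$label)) < 3L) {
    stop("train_profile_model: all three profiles must be present",
         call. = FALSE)
  }
  cols <- setdiff(names(features), c("label", "subject_id"))
  x <- as.matrix(features[, cols, drop = FALSE])
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  scale_[scale_ <= 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  set.seed(seed)
  fit <- switch(algorithm,
    svm = e1071::svm(x = xs, y = labs, kernel = "radial", scale = FALSE),
    naive_bayes = e1071::naiveBayes(x = as.data.frame(xs), y = labs),
    mlp = nnet::nnet(x = xs, y = stats::model.matrix(~ labs - 1),
                     size = 8L, maxit = 500L, softmax = TRUE, trace = FALSE),
    random_forest = ranger::ranger(x = as.data.frame(xs), y = labs,
                                   num.trees = 500L, probability = TRUE,
                                   seed = seed, num.threads = 1L))
  structure(list(algorithm = algorithm, fit = fit, feature_names = cols,
                 center = center, scale = scale_, seed = seed),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model> %s, %d features\n", x$algorithm,
              length(x$feature_names)))
  invisible(x)
}

#' Classify psychological profiles
#'
#' @param model A `profile_model`.
#' @param features Data frame with the model's feature columns.
#' @return Character vector of profiles in
#'   `{motivated, anxious, depressed}`.
#' @export
classify_profile <- function(model, features) {
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing) > 0L) {
    stop("classify_profile: feature schema mismatch, missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  out <- switch(model$algorithm,
    svm = as.character(stats::predict(model$fit, xs)),
    naive_bayes = as.character(stats::predict(model$fit, as.data.frame(xs))),
    mlp = {
      pr <- stats::predict(model$fit, xs)
      sub("^labs", "", colnames(pr)[max.col(pr)])
    },
    random_forest = {
      pr <- stats::predict(model$fit, data = as.data.frame(xs),
                           num.threads = 1L)$predictions
      colnames(pr)[max.col(pr, ties.method = "first")]
    })
  out
}

#' Leave-one-subject-out evaluation of profile recognition
#'
#' Same harness contract as the activity module: per-subject folds pooled
#' into one confusion matrix, with the majority-class baseline accuracy
#' computed alongside.
#'
#' @param features Data frame with `label`, `subject_id` and numeric
#'   feature columns.
#' @param algorithm Learner name (see [train_profile_model()]).
#' @param seed Integer seed.
#' @return A `classification_eval` with extra elements `majority_accuracy`
#'   (percent) and `folds`.
#' @export
evaluate_profile_loso <- function(features, algorithm = "svm", seed = 1L) {
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2L) {
    stop("evaluate_profile_loso: need >= 2 subjects", call. = FALSE)
  }
  truth <- character(0); pred <- character(0); base <- character(0)
  folds <- list()
  for (s in subjects) {
    test <- features[features$subject_id == s, , drop = FALSE]
    train <- features[features$subject_id != s, , drop = FALSE]
    fit <- train_profile_model(train, algorithm, seed)
    p <- classify_profile(fit, test)
    maj <- names(sort(table(train$label), decreasing = TRUE))[1L]
    truth <- c(truth, test$label)
    pred <- c(pred, p)
    base <- c(base, rep(maj, nrow(test)))
    folds[[s]] <- data.frame(subject_id = s, n = nrow(test),
                             accuracy = 100 * mean(p == test$label))
  }
  ev <- classification_metrics(truth, pred, levels = psych_profiles())
  ev$majority_accuracy <- 100 * mean(base == truth)
  ev$folds <- do.call(rbind, folds)
  rownames(ev$folds) <- NULL
  ev
}

#' Festinger cognitive-dissonance principle for a profile
#'
#' Fixed mapping from psychological profile to the cognitive behavioral
#' message principle used to phrase interventions: motivated patients
#' receive messages built on the cognitive consequences of forced
#' compliance, anxious patients on free choice, and depressed patients on
#' effort justification.
#'
#' @param profile One of `"motivated"`, `"anxious"`, `"depressed"`.
#' @return The principle name (character scalar).
#' @export
select_cbt_principle <- function(profile) {
  profile <- match.arg(profile, psych_profiles())
  switch(profile,
    motivated = "cognitive consequences of forced compliance",
    anxious = "free choice",
    depressed = "effort justification")
}
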
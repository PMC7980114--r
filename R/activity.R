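#' The closed set of recognized physical activities
#' @return Character vector of the 10 activity labels.
#' @export
activity_labels <- function() {
  c("rest", "standing", "walking", "nordic_walking", "running", "exercise",
    "eating", "washing", "chores", "hand_activities")
}

lowpass_axis <- function(v, rate, cutoff, order = 4L) {
  cutoff <- min(cutoff, 0.45 * rate)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  filtfilt_padded(bf, v, pad = round(3 * rate / cutoff))
}

#' Separate an accelerometer stream into gravity and dynamic components
#'
#' The stream is first low-pass filtered at 10 Hz to remove sensor noise;
#' the gravity component is the 0.3 Hz low-pass of the denoised signal, and
#' the dynamic (human-motion) component is their difference, which realizes
#' the 0.3-10 Hz band-pass by subtraction so that gravity + dynamic
#' reconstructs the denoised stream exactly.
#'
#' @param stream An `accel_stream` with rate >= 20 Hz.
#' @param noise_cutoff Noise low-pass cutoff in Hz (default 10).
#' @param gravity_cutoff Gravity low-pass cutoff in Hz (default 0.3).
#' @return List with `gravity` and `dynamic`, each a list of `x`, `y`, `z`
#'   vectors, plus `t` and `rate`.
#' @export
split_components <- function(stream, noise_cutoff = 10, gravity_cutoff = 0.3) {
  stopifnot(inherits(stream, "accel_stream"))
  if (stream$rate < 20) {
    stop("split_components: sampling rate must be >= 20 Hz", call. = FALSE)
  }
  den <- lapply(stream[c("x", "y", "z")], lowpass_axis, rate = stream$rate,
                cutoff = noise_cutoff, order = 4L)
  grav <- lapply(den, lowpass_axis, rate = stream$rate,
                 cutoff = gravity_cutoff, order = 2L)
  dyn <- Map(`-`, den, grav)
  list(gravity = grav, dynamic = dyn, denoised = den,
       t = stream$t, rate = stream$rate, subject_id = stream$subject_id)
}

#' Segment a component-split stream into fixed windows
#'
#' Consecutive non-overlapping windows of `length_s` seconds; a trailing
#' partial window is dropped. When per-sample labels are available the
#' window label is the majority label of its samples.
#'
#' @param comp Result of [split_components()].
#' @param length_s Window length in seconds (default 2).
#' @param labels Optional per-sample label vector (training data).
#' @return List of `activity_window` objects with `gravity`, `dynamic`
#'   (3-axis lists), `start_s`, `rate` and optional `label`.
#' @export
segment_windows <- function(comp, length_s = 2, labels = NULL) {
  if (length_s <= 0) stop("segment_windows: length must be > 0", call. = FALSE)
  n <- length(comp$t)
  w <- round(length_s * comp$rate)
  n_win <- n %/% w
  out <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    idx <- ((k - 1L) * w + 1L):(k * w)
    lab <- if (is.null(labels)) NA_character_ else {
      names(sort(table(labels[idx]), decreasing = TRUE))[1L]
    }
    out[[k]] <- structure(
      list(gravity = lapply(comp$gravity, `[`, idx),
           dynamic = lapply(comp$dynamic, `[`, idx),
           start_s = comp$t[idx[1L]], rate = comp$rate, label = lab),
      class = "activity_window"
    )
  }
  out
}

skew0 <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0) return(0)
  mean(((v - mean(v)) / s)^3)
}
kurt0 <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0) return(0)
  mean(((v - mean(v)) / s)^4) - 3
}

count_mean_crossings <- function(v) {
  s <- v - mean(v)
  s <- s[s != 0]
  if (length(s) < 2L) return(0)
  sum(s[-1L] * s[-length(s)] < 0)
}

count_peaks <- function(v, prominence = 0.05) {
  n <- length(v)
  if (n < 3L) return(0)
  cnt <- 0L
  for (i in 2L:(n - 1L)) {
    if (v[i] > v[i - 1L] && v[i] >= v[i + 1L]) {
      left <- min(v[1L:i])
      right <- min(v[i:n])
      if (v[i] - max(left, right) >= prominence) cnt <- cnt + 1L
    }
  }
  cnt
}

#' Feature vector for one activity window
#'
#' The documented 65-feature set covering the standard wrist-accelerometer
#' categories: dynamic-component statistics per axis and magnitude (mean,
#' variance, skewness, kurtosis, min, max, range, RMS, IQR, median absolute
#' deviation = 40); physics-based velocity change (integral of |a| dt) and
#' kinetic-energy proxy (mean a^2) per axis and magnitude (8); signal-shape
#' counts per axis and magnitude: peaks with prominence >= 0.05 g and
#' mean crossings (8); inter-axis correlations of the dynamic component (3);
#' orientation: gravity per-axis means and inclination angles of the mean
#' gravity vector to each axis (6). Zero-variance inputs yield skewness and
#' kurtosis 0 by convention.
#'
#' @param window An `activity_window`.
#' @param peak_prominence Peak prominence threshold in g (default 0.05).
#' @return Named numeric vector of length 65.
#' @export
extract_activity_features <- function(window, peak_prominence = 0.05) {
  dyn <- window$dynamic
  dt <- 1 / window$rate
  mag <- sqrt(dyn$x^2 + dyn$y^2 + dyn$z^2)
  chans <- list(x = dyn$x, y = dyn$y, z = dyn$z, mag = mag)
  stats_one <- function(v, nm) {
    out <- c(mean(v), stats::var(v), skew0(v), kurt0(v), min(v), max(v),
             max(v) - min(v), sqrt(mean(v^2)), stats::IQR(v),
             stats::mad(v),
             sum(abs(v)) * dt, mean(v^2),
             count_peaks(v, peak_prominence), count_mean_crossings(v))
    names(out) <- paste0(nm, "_", c("mean", "var", "skew", "kurt", "min",
                                    "max", "range", "rms", "iqr", "mad",
                                    "vel_change", "kinetic", "peaks",
                                    "crossings"))
    out
  }
  dyn_feats <- unlist(lapply(names(chans), function(nm) stats_one(chans[[nm]], nm)))
  cors <- c(
    xy_cor = safe_cor(dyn$x, dyn$y),
    xz_cor = safe_cor(dyn$x, dyn$z),
    yz_cor = safe_cor(dyn$y, dyn$z))
  g <- vapply(window$gravity, mean, numeric(1))
  gn <- sqrt(sum(g^2))
  ang <- if (gn > 0) acos(pmin(pmax(g / gn, -1), 1)) else c(0, 0, 0)
  grav_feats <- c(gx_mean = unname(g[1L]), gy_mean = unname(g[2L]),
                  gz_mean = unname(g[3L]),
                  incl_x = unname(ang[1L]), incl_y = unname(ang[2L]),
                  incl_z = unname(ang[3L]))
  c(dyn_feats, cors, grav_feats)
}

safe_cor <- function(a, b) {
  if (stats::sd(a) <= 0 || stats::sd(b) <= 0) return(0)
  stats::cor(a, b)
}

activity_feature_table <- function(windows, peak_prominence = 0.05) {
  feats <- as.data.frame(do.call(rbind, lapply(windows,
                                               extract_activity_features,
                                               peak_prominence = peak_prominence)))
  feats$label <- vapply(windows, function(w) w$label, character(1))
  feats$start_s <- vapply(windows, function(w) w$start_s, numeric(1))
  feats
}

#' Train the activity classifier
#'
#' Random-forest classifier over the 10-activity label set, trained on
#' labeled window features.
#'
#' @param features Data frame from windows (see
#'   [extract_activity_features()]) with a `label` column; >= 2 classes
#'   required.
#' @param seed Integer seed.
#' @param num_trees Number of trees (default 500).
#' @return An `activity_model` object.
#' @export
train_activity_model <- function(features, seed = 1L, num_trees = 500L) {
  labs <- features$label
  if (length(unique(labs)) < 2L) {
    stop("train_activity_model: need >= 2 classes in training data",
         call. = FALSE)
  }
  cols <- setdiff(names(features), c("label", "start_s", "subject_id"))
  lev <- intersect(activity_labels(), unique(labs))
  fit <- ranger::ranger(x = features[, cols, drop = FALSE],
                        y = factor(labs, levels = lev),
                        num.trees = num_trees, probability = TRUE,
                        seed = seed, num.threads = 1L)
  structure(list(fit = fit, feature_names = cols, seed = seed),
            class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity_model> random forest, %d trees, %d features\n",
              x$fit$num.trees, length(x$feature_names)))
  invisible(x)
}

#' Classify activity windows
#'
#' @param model An `activity_model`.
#' @param features Data frame of window features.
#' @return Data frame with `label` (one of the 10 activities) and
#'   `confidence` (class probability).
#' @export
classify_window <- function(model, features) {
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing) > 0L) {
    stop("classify_window: feature schema mismatch, missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pr <- stats::predict(model$fit,
                       data = features[, model$feature_names, drop = FALSE],
                       num.threads = 1L)$predictions
  j <- max.col(pr, ties.method = "first") # fixed tie-break for determinism
  data.frame(label = colnames(pr)[j],
             confidence = pr[cbind(seq_len(nrow(pr)), j)])
}

#' Leave-one-subject-out evaluation of activity recognition
#'
#' Trains one model per held-out subject and pools the fold predictions into
#' a single confusion matrix, from which per-class precision/recall/F and
#' macro averages are computed.
#'
#' @param features Window-feature data frame with `label` and `subject_id`
#'   columns, >= 2 subjects.
#' @param seed Integer seed.
#' @param num_trees Trees per fold model (default 500).
#' @return A `classification_eval` (see [classification_metrics()]) with an
#'   extra `folds` element listing per-subject accuracy.
#' @export
evaluate_activity_loso <- function(features, seed = 1L, num_trees = 500L) {
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2L) {
    stop("evaluate_activity_loso: need >= 2 subjects", call. = FALSE)
  }
  truth <- character(0)
  pred <- character(0)
  folds <- list()
  for (s in subjects) {
    test <- features[features$subject_id == s, , drop = FALSE]
    train <- features[features$subject_id != s, , drop = FALSE]
    fit <- train_activity_model(train, seed = seed, num_trees = num_trees)
    p <- classify_window(fit, test)$label
    truth <- c(truth, test$label)
    pred <- c(pred, p)
    folds[[s]] <- data.frame(subject_id = s, n = nrow(test),
                             accuracy = 100 * mean(p == test$label))
  }
  ev <- classification_metrics(truth, pred,
                               levels = intersect(activity_labels(),
                                                  unique(c(truth, pred))))
  ev$folds <- do.call(rbind, folds)
  rownames(ev$folds) <- NULL
  ev
}
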
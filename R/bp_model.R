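#' Construct a table of cuff BP ground-truth readings
#'
#' @param timestamp Reading times in seconds.
#' @param sbp,dbp Systolic and diastolic pressure in mm Hg
#'   (30 < dbp < sbp < 300).
#' @param subject_id Subject identifier (recycled).
#' @return A `bp_readings` data frame: `subject_id`, `timestamp`, `sbp`,
#'   `dbp`, ordered by time.
#' @export
bp_readings <- function(timestamp, sbp, dbp, subject_id = "s1") {
  stopifnot(length(timestamp) == length(sbp), length(sbp) == length(dbp))
  if (any(!(30 < dbp & dbp < sbp & sbp < 300))) {
    stop("bp_readings: need 30 < dbp < sbp < 300 mm Hg", call. = FALSE)
  }
  out <- data.frame(subject_id = subject_id, timestamp = as.numeric(timestamp),
                    sbp = as.numeric(sbp), dbp = as.numeric(dbp))
  out[order(out$timestamp), , drop = FALSE]
}

#' Pair per-cycle features with the nearest ground-truth reading
#'
#' Each feature row is attributed to the nearest cuff reading within the
#' pairing tolerance (the signal 30 s before and after each measurement, by
#' default); ties go to the earlier reading. Rows outside every tolerance
#' window are dropped.
#'
#' @param features Feature data frame from [ppg_session_features()] (must
#'   contain `timestamp_s` and `subject_id`).
#' @param readings A `bp_readings` data frame for the same subject.
#' @param tolerance Pairing tolerance in seconds (default 30).
#' @return A labeled-instance data frame: the feature columns plus `sbp`,
#'   `dbp` and `reading_id` (index of the paired reading).
#' @export
pair_with_ground_truth <- function(features, readings, tolerance = 30) {
  if (nrow(features) == 0L) return(cbind(features, sbp = numeric(), dbp = numeric()))
  idx <- integer(nrow(features))
  for (i in seq_len(nrow(features))) {
    d <- abs(features$timestamp_s[i] - readings$timestamp)
    j <- which(d <= tolerance)
    if (length(j) == 0L) {
      idx[i] <- NA_integer_
    } else {
      # nearest reading; ties broken toward the earlier reading
      dj <- d[j]
      idx[i] <- j[which(dj == min(dj))[1L]]
    }
  }
  keep <- !is.na(idx)
  out <- features[keep, , drop = FALSE]
  out$sbp <- readings$sbp[idx[keep]]
  out$dbp <- readings$dbp[idx[keep]]
  out$reading_id <- idx[keep]
  rownames(out) <- NULL
  out
}

#' Mean absolute error
#'
#' @param predictions,truth Equal-length numeric vectors (mm Hg).
#' @return Mean of `|predictions - truth|`.
#' @export
mean_absolute_error <- function(predictions, truth) {
  if (length(predictions) != length(truth) || length(truth) < 1L) {
    stop("mean_absolute_error: length mismatch", call. = FALSE)
  }
  mean(abs(predictions - truth))
}

bp_feature_cols <- function(instances) {
  setdiff(names(instances),
          c("subject_id", "timestamp_s", "sbp", "dbp", "reading_id"))
}

fit_one_regressor <- function(x, y, algorithm, seed, hyperparams) {
  set.seed(seed)
  df <- as.data.frame(x)
  df$.y <- y
  switch(algorithm,
    dummy_mean = list(kind = "dummy_mean", mean = mean(y)),
    decision_tree = list(kind = "decision_tree",
                         fit = rpart::rpart(.y ~ ., data = df,
                                            method = "anova")),
    knn = list(kind = "knn",
               fit = caret::knnreg(as.matrix(x), y,
                                   k = hyperparams$knn_k %||% 5L)),
    svr = list(kind = "svr",
               fit = e1071::svm(x = as.matrix(x), y = y, kernel = "radial",
                                scale = FALSE)),
    random_forest = list(kind = "random_forest",
                         fit = ranger::ranger(
                           x = as.data.frame(x), y = y,
                           num.trees = hyperparams$num_trees %||% 500L,
                           # standard regression-forest default (p/3) and
                           # fully grown trees
                           mtry = hyperparams$mtry %||%
                             max(floor(ncol(x) / 3), 1L),
                           min.node.size = hyperparams$min_node_size %||% 1L,
                           seed = seed, num.threads = 1L)),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

predict_one_regressor <- function(model, x) {
  x <- as.data.frame(x)
  switch(model$kind,
    dummy_mean = rep(model$mean, nrow(x)),
    decision_tree = unname(stats::predict(model$fit, newdata = x)),
    knn = unname(stats::predict(model$fit, as.matrix(x))),
    svr = unname(stats::predict(model$fit, as.matrix(x))),
    random_forest = stats::predict(model$fit, data = x,
                                   num.threads = 1L)$predictions
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a blood-pressure regression model
#'
#' Fits paired SBP and DBP regressors of the chosen family on labeled
#' instances. Features are standardized with training-set statistics only
#' (stored in the model and reapplied at prediction time). The
#' `dummy_mean` baseline always predicts the training means.
#'
#' @param instances Labeled-instance data frame from
#'   [pair_with_ground_truth()].
#' @param algorithm One of `"dummy_mean"`, `"decision_tree"`, `"knn"`,
#'   `"svr"`, `"random_forest"`.
#' @param seed Integer seed controlling all fitting randomness.
#' @param hyperparams Named list: `num_trees` (random forest, default 500),
#'   `knn_k` (default 5).
#' @return A `bp_model` object.
#' @export
train_bp_model <- function(instances, algorithm = "random_forest", seed = 1L,
                           hyperparams = list()) {
  algorithm <- match.arg(algorithm, c("dummy_mean", "decision_tree", "knn",
                                      "svr", "random_forest"))
  if (nrow(instances) < 10L) {
    stop("train_bp_model: need at least 10 instances", call. = FALSE)
  }
  cols <- bp_feature_cols(instances)
  x <- as.matrix(instances[, cols, drop = FALSE])
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  scale_[scale_ <= 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  structure(
    list(algorithm = algorithm,
         sbp = fit_one_regressor(xs, instances$sbp, algorithm, seed, hyperparams),
         dbp = fit_one_regressor(xs, instances$dbp, algorithm, seed + 1L,
                                 hyperparams),
         feature_names = cols, center = center, scale = scale_,
         n = nrow(instances), seed = seed,
         subjects = unique(instances$subject_id)),
    class = "bp_model"
  )
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> %s, %d instances, %d features, subjects: %s\n",
              x$algorithm, x$n, length(x$feature_names),
              paste(x$subjects, collapse = ", ")))
  invisible(x)
}

#' Predict SBP and DBP for new feature rows
#'
#' @param object A `bp_model`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Data frame with columns `sbp`, `dbp` (mm Hg, clipped to
#'   \[30, 300\]).
#' @export
predict.bp_model <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing) > 0L) {
    stop("predict.bp_model: feature schema mismatch, missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  clip <- function(v) pmin(pmax(v, 30), 300)
  data.frame(sbp = clip(predict_one_regressor(object$sbp, xs)),
             dbp = clip(predict_one_regressor(object$dbp, xs)))
}

#' Alias for predicting BP from a model
#' @inheritParams predict.bp_model
#' @param model A `bp_model`.
#' @export
predict_bp <- function(model, newdata) predict(model, newdata)

#' Leave-one-subject-out evaluation of BP estimation
#'
#' One fold per subject: the model is trained on all other subjects and
#' tested on the held-out one, with the dummy-mean baseline computed on the
#' same folds. Reports per-fold and mean MAE for SBP and DBP.
#'
#' @param instances Labeled instances covering >= 2 subjects.
#' @param algorithm Learner name (see [train_bp_model()]).
#' @param seed Integer seed.
#' @param hyperparams Passed to [train_bp_model()].
#' @return A `bp_eval` list: `folds` (data frame with per-subject MAEs for
#'   the model and the dummy baseline), `mae_sbp`, `mae_dbp`,
#'   `dummy_mae_sbp`, `dummy_mae_dbp`.
#' @export
evaluate_loso <- function(instances, algorithm = "random_forest", seed = 1L,
                          hyperparams = list()) {
  subjects <- unique(instances$subject_id)
  if (length(subjects) < 2L) {
    stop("evaluate_loso: need at least 2 subjects", call. = FALSE)
  }
  rows <- list()
  for (s in subjects) {
    test <- instances[instances$subject_id == s, , drop = FALSE]
    train <- instances[instances$subject_id != s, , drop = FALSE]
    if (nrow(test) == 0L) {
      warning("evaluate_loso: subject ", s, " has no instances; skipped")
      next
    }
    fit <- train_bp_model(train, algorithm, seed, hyperparams)
    stopifnot(!(s %in% fit$subjects)) # leakage guard
    pr <- predict(fit, test)
    dummy <- train_bp_model(train, "dummy_mean", seed)
    pd <- predict(dummy, test)
    rows[[s]] <- data.frame(
      subject_id = s, n = nrow(test),
      mae_sbp = mean_absolute_error(pr$sbp, test$sbp),
      mae_dbp = mean_absolute_error(pr$dbp, test$dbp),
      dummy_mae_sbp = mean_absolute_error(pd$sbp, test$sbp),
      dummy_mae_dbp = mean_absolute_error(pd$dbp, test$dbp))
  }
  folds <- do.call(rbind, rows)
  rownames(folds) <- NULL
  structure(
    list(folds = folds, fold_type = "subject", algorithm = algorithm,
         mae_sbp = mean(folds$mae_sbp), mae_dbp = mean(folds$mae_dbp),
         dummy_mae_sbp = mean(folds$dummy_mae_sbp),
         dummy_mae_dbp = mean(folds$dummy_mae_dbp)),
    class = "bp_eval"
  )
}

#' Personalized chronological 70/30 evaluation
#'
#' Splits one subject's instances at BP-reading granularity: readings are
#' ordered in time and the earliest 70% (with all their paired cycles) form
#' the training set, so no reading's cycles straddle the split and training
#' strictly precedes testing.
#'
#' @param instances Labeled instances of a single subject (must carry
#'   `reading_id`).
#' @param train_frac Fraction of readings assigned to training (default 0.7).
#' @param algorithm Learner name.
#' @param seed Integer seed.
#' @param hyperparams Passed to [train_bp_model()].
#' @return A `bp_eval` list with `mae_sbp`, `mae_dbp`, `dummy_mae_sbp`,
#'   `dummy_mae_dbp`, plus `split` metadata (`train_readings`,
#'   `test_readings`, `max_train_time`, `min_test_time`).
#' @export
evaluate_personalized <- function(instances, train_frac = 0.7,
                                  algorithm = "random_forest", seed = 1L,
                                  hyperparams = list()) {
  stopifnot("reading_id" %in% names(instances))
  rids <- sort(unique(instances$reading_id))
  if (length(rids) < 4L) {
    stop("evaluate_personalized: need >= 4 distinct readings", call. = FALSE)
  }
  # readings are chronologically ordered by construction of bp_readings
  n_train <- floor(train_frac * length(rids))
  train_r <- rids[seq_len(n_train)]
  test_r <- setdiff(rids, train_r)
  train <- instances[instances$reading_id %in% train_r, , drop = FALSE]
  test <- instances[instances$reading_id %in% test_r, , drop = FALSE]
  stopifnot(max(train$timestamp_s) < min(test$timestamp_s)) # leakage guard
  fit <- train_bp_model(train, algorithm, seed, hyperparams)
  pr <- predict(fit, test)
  dummy <- train_bp_model(train, "dummy_mean", seed)
  pd <- predict(dummy, test)
  structure(
    list(fold_type = "chronological", algorithm = algorithm,
         mae_sbp = mean_absolute_error(pr$sbp, test$sbp),
         mae_dbp = mean_absolute_error(pr$dbp, test$dbp),
         dummy_mae_sbp = mean_absolute_error(pd$sbp, test$sbp),
         dummy_mae_dbp = mean_absolute_error(pd$dbp, test$dbp),
         split = list(train_readings = train_r, test_readings = test_r,
                      max_train_time = max(train$timestamp_s),
                      min_test_time = min(test$timestamp_s))),
    class = "bp_eval"
  )
}

#' @export
print.bp_eval <- function(x, ...) {
  cat(sprintf("<bp_eval> %s (%s folds)\n", x$algorithm, x$fold_type))
  cat(sprintf("  MAE SBP %.2f mm Hg (dummy %.2f), MAE DBP %.2f mm Hg (dummy %.2f)\n",
              x$mae_sbp, x$dummy_mae_sbp, x$mae_dbp, x$dummy_mae_dbp))
  invisible(x)
}
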
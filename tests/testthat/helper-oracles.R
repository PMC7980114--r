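# Independent brute-force oracles used across test files. These deliberately
# use different code paths (stats::median/mad, plain loops) than the package.

oracle_hampel <- function(x, half_window, n_sigmas) {
  n <- length(x)
  y <- x
  for (i in seq_len(n)) {
    w <- x[max(1, i - half_window):min(n, i + half_window)]
    m <- stats::median(w)
    s <- stats::mad(w, constant = 1.4826)
    if (is.finite(s) && abs(x[i] - m) > n_sigmas * s) y[i] <- m
  }
  y
}

oracle_dummy_mae <- function(train_targets, test_targets) {
  mean(abs(test_targets - mean(train_targets)))
}

oracle_prf <- function(truth, pred, levels) {
  per <- lapply(levels, function(l) {
    tp <- sum(truth == l & pred == l)
    fp <- sum(truth != l & pred == l)
    fn <- sum(truth == l & pred != l)
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else
      if (!is.na(p) && !is.na(r)) 0 else NA_real_
    c(p = p, r = r, f = f)
  })
  do.call(rbind, per)
}

oracle_rmssd <- function(iv) {
  acc <- 0
  for (k in 2:length(iv)) acc <- acc + (iv[k] - iv[k - 1])^2
  sqrt(acc / (length(iv) - 1))
}

oracle_nds_rank <- function(pts) {
  n <- nrow(pts)
  dominated_by <- function(i, j) { # j dominates i
    all(pts[j, ] <= pts[i, ]) && any(pts[j, ] < pts[i, ])
  }
  rank <- rep(NA_integer_, n)
  r <- 1L
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    front <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) i != j && dominated_by(i, j),
                  logical(1)))
    }, logical(1))]
    rank[front] <- r
    remaining <- setdiff(remaining, front)
    r <- r + 1L
  }
  rank
}

# small labeled BP instance table for harness tests: two informative
# features, three subjects
make_toy_instances <- function(n_per_subject = 12, seed = 42) {
  set.seed(seed)
  rows <- lapply(1:3, function(s) {
    f1 <- runif(n_per_subject)
    f2 <- runif(n_per_subject)
    data.frame(subject_id = sprintf("s%d", s),
               timestamp_s = seq_len(n_per_subject) * 10,
               feat_a = f1, feat_b = f2,
               sbp = 100 + 40 * f1 + rnorm(n_per_subject, 0, 1),
               dbp = 60 + 25 * f2 + rnorm(n_per_subject, 0, 1),
               reading_id = seq_len(n_per_subject))
  })
  do.call(rbind, rows)
}

# simple wellbeing toolchain for recommender tests
make_toy_dss <- function(rule, n = 500, seed = 31, model_seed = 3,
                         modifiable = c("temperature", "humidity")) {
  ds <- gen_wellbeing_dataset(n, rule = rule, noise = 0.02, seed = seed)
  model <- train_health_model(ds$records, seed = model_seed)
  part <- fit_correlated_models(ds$records,
                                partition_features(ds$records, modifiable))
  list(records = ds$records, model = model, partition = part,
       bounds = list(temperature = c(-10, 10), humidity = c(-30, 30)))
}

axis_grid_oracle <- function(rec, model, var, bounds, step = 0.01) {
  grid <- seq(bounds[[var]][1], bounds[[var]][2], by = step)
  cand <- rec[rep(1, length(grid)), , drop = FALSE]
  cand[[var]] <- rec[[var]] + grid
  adm <- predict(model, cand) == "good"
  if (!any(adm)) return(Inf)
  min(abs(grid)[adm]) / model$ranges[[var]]
}
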
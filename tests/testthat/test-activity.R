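test_that("component separation recovers gravity and dynamic motion", {
  rate <- 50
  n <- 20 * rate
  t <- (seq_len(n) - 1) / rate

  # static device: gravity = (0,0,1), dynamic ~ 0
  still <- accel_stream(t, rep(0, n), rep(0, n), rep(1, n), rate)
  comp <- split_components(still)
  expect_equal(mean(comp$gravity$z), 1, tolerance = 1e-3)
  expect_lt(sqrt(mean(comp$dynamic$z^2)), 1e-3)

  # 2 Hz oscillation on gravity: dynamic recovers the amplitude within 5%
  osc <- accel_stream(t, 0.3 * sin(2 * pi * 2 * t), rep(0, n), rep(1, n), rate)
  comp2 <- split_components(osc)
  mid <- seq(2 * rate, n - 2 * rate)
  amp <- sqrt(2) * sqrt(mean(comp2$dynamic$x[mid]^2))
  expect_equal(amp, 0.3, tolerance = 0.05 * 0.3)

  # reconstruction: gravity + dynamic = denoised within 1e-3 g RMS
  recon <- comp2$gravity$x + comp2$dynamic$x - comp2$denoised$x
  expect_lt(sqrt(mean(recon^2)), 1e-3)

  slow <- accel_stream(t[1:40], rep(0, 40), rep(0, 40), rep(1, 40), 10)
  expect_error(split_components(slow), ">= 20 Hz")
})

test_that("window segmentation drops trailing partials and keeps contiguity", {
  rate <- 50
  mk <- function(sec) {
    n <- sec * rate
    split_components(accel_stream((seq_len(n) - 1) / rate, rnorm(n, 0, 0.01),
                                  rnorm(n, 0, 0.01), 1 + rnorm(n, 0, 0.01),
                                  rate))
  }
  expect_length(segment_windows(mk(10)), 5)
  expect_length(segment_windows(mk(11)), 5) # partial dropped
  wins <- segment_windows(mk(10))
  starts <- vapply(wins, function(w) w$start_s, numeric(1))
  expect_equal(diff(starts), rep(2, 4))
})

test_that("activity features follow closed-form counts on constructed windows", {
  rate <- 50
  n <- 2 * rate
  mkwin <- function(x, y = rep(0, n), z = rep(0, n), g = c(0, 0, 1)) {
    structure(list(gravity = list(x = rep(g[1], n), y = rep(g[2], n),
                                  z = rep(g[3], n)),
                   dynamic = list(x = x, y = y, z = z),
                   start_s = 0, rate = rate, label = NA_character_),
              class = "activity_window")
  }

  # constant window: zero variance, zero counts
  f0 <- extract_activity_features(mkwin(rep(0, n)))
  expect_equal(unname(f0["x_var"]), 0)
  expect_equal(unname(f0["x_peaks"]), 0)
  expect_equal(unname(f0["x_crossings"]), 0)
  expect_equal(unname(f0["x_skew"]), 0) # zero-variance convention
  expect_length(f0, 65)

  # 2 Hz sinusoid over 2 s: 2 f T = 8 mean crossings, f T = 4 peaks
  t <- (seq_len(n) - 1) / rate
  s <- sin(2 * pi * 2 * t + 0.3)
  fs <- extract_activity_features(mkwin(s))
  expect_equal(unname(fs["x_crossings"]), 8)
  expect_equal(unname(fs["x_peaks"]), 4)

  # gravity orientation: inclination of (0,0,1) to z is 0, to x is pi/2
  expect_equal(unname(f0["incl_z"]), 0)
  expect_equal(unname(f0["incl_x"]), pi / 2)
})

test_that("classification metrics equal the confusion-matrix oracle", {
  # hand-checked toy confusion [[8,2],[4,6]]
  truth <- c(rep("a", 10), rep("b", 10))
  pred <- c(rep("a", 8), rep("b", 2), rep("a", 4), rep("b", 6))
  ev <- classification_metrics(truth, pred)
  expect_equal(ev$per_class$precision[ev$per_class$class == "a"], 100 * 8 / 12,
               tolerance = 1e-9)
  expect_equal(ev$per_class$recall[ev$per_class$class == "a"], 80)
  expect_equal(ev$per_class$f_measure[ev$per_class$class == "a"],
               2 * (200 / 3) * 80 / (200 / 3 + 80), tolerance = 1e-9)
  expect_equal(ev$macro_f, mean(ev$per_class$f_measure))

  # perfect predictions
  evp <- classification_metrics(truth, truth)
  expect_equal(evp$macro_f, 100)
  expect_equal(evp$accuracy, 100)

  # property: random label vectors match the independent oracle
  set.seed(33)
  for (rep_i in 1:5) {
    lv <- letters[1:4]
    tr <- sample(lv, 60, replace = TRUE)
    pr <- sample(lv, 60, replace = TRUE)
    got <- classification_metrics(tr, pr, levels = lv)
    want <- oracle_prf(tr, pr, lv)
    expect_equal(got$per_class$precision, unname(want[, "p"]))
    expect_equal(got$per_class$recall, unname(want[, "r"]))
    expect_equal(got$per_class$f_measure, unname(want[, "f"]))
  }
})

test_that("activity model separates synthetic regimes and rejects degenerate input", {
  feats <- list()
  for (s in 1:2) {
    ses <- gen_activity_session(list(list("rest", 30), list("running", 30)),
                                seed = 200 + s, subject_id = paste0("s", s))
    wins <- segment_windows(split_components(ses), labels = ses$labels)
    f <- pulseman:::activity_feature_table(wins)
    f$subject_id <- paste0("s", s)
    feats[[s]] <- f
  }
  feats <- do.call(rbind, feats)
  train <- feats[feats$subject_id == "s1", ]
  test <- feats[feats$subject_id == "s2", ]
  fit <- train_activity_model(train, seed = 4, num_trees = 100)
  pred <- classify_window(fit, test)
  expect_gte(mean(pred$label == test$label), 0.95)
  expect_true(all(pred$label %in% activity_labels()))
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))

  only_rest <- train[train$label == "rest", ]
  expect_error(train_activity_model(only_rest), "2 classes")
})
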
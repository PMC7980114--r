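test_that("mean absolute error follows its definition and invariances", {
  expect_equal(mean_absolute_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mean_absolute_error(c(120, 130), c(118, 134)), 3.0)
  # translation invariance
  expect_equal(mean_absolute_error(c(120, 130) + 7, c(118, 134) + 7), 3.0)
  expect_error(mean_absolute_error(1:3, 1:2), "length mismatch")
})

test_that("ground-truth pairing respects tolerance, nearest reading and tie rule", {
  feats <- data.frame(subject_id = "s1",
                      timestamp_s = c(100, 100, 118, 300),
                      feat_a = 1:4)
  rd <- bp_readings(timestamp = c(110, 131, 140), sbp = c(120, 125, 130),
                    dbp = c(80, 82, 84))
  out <- pair_with_ground_truth(feats, rd, tolerance = 30)
  # cycle at 100 is within 30 s of reading at 110 -> paired
  expect_true(100 %in% out$timestamp_s)
  # cycle at 300 is outside all tolerances -> dropped
  expect_false(300 %in% out$timestamp_s)
  # cycle at 118: distance 8 to reading 1, 13 to reading 2 -> nearest wins
  expect_equal(out$sbp[out$timestamp_s == 118], 120)

  # exact tie: equidistant cycle pairs with the earlier reading
  feats2 <- data.frame(subject_id = "s1", timestamp_s = 120.5, feat_a = 1)
  rd2 <- bp_readings(timestamp = c(110, 131), sbp = c(120, 125),
                     dbp = c(80, 82))
  out2 <- pair_with_ground_truth(feats2, rd2, tolerance = 30)
  expect_equal(out2$sbp, 120)
})

test_that("dummy model predicts training means; learners beat it on informative data", {
  inst <- make_toy_instances(seed = 42)
  dummy <- train_bp_model(inst, "dummy_mean", seed = 1)
  pred <- predict(dummy, inst[1:5, ])
  expect_true(all(pred$sbp == mean(inst$sbp)))
  expect_true(all(pred$dbp == mean(inst$dbp)))

  # two-target toy: dummy returns 125 for any input
  small <- inst[1:10, ]
  small$sbp <- rep(c(120, 130), 5)
  small$dbp <- rep(c(70, 90), 5)
  d2 <- train_bp_model(small, "dummy_mean", seed = 1)
  expect_equal(predict(d2, small[3, ])$sbp, 125)

  rf <- train_bp_model(inst, "random_forest", seed = 2)
  pr <- predict(rf, inst)
  pd <- predict(dummy, inst)
  expect_lt(mean_absolute_error(pr$sbp, inst$sbp),
            mean_absolute_error(pd$sbp, inst$sbp))

  # determinism: same data + seed -> identical predictions
  rf2 <- train_bp_model(inst, "random_forest", seed = 2)
  expect_identical(predict(rf2, inst), pr)

  # all five algorithms fit and predict finite clipped values
  for (alg in c("dummy_mean", "decision_tree", "knn", "svr", "random_forest")) {
    m <- train_bp_model(inst, alg, seed = 3)
    p <- predict(m, inst[1:4, ])
    expect_true(all(is.finite(p$sbp)) && all(is.finite(p$dbp)))
    expect_true(all(p$sbp >= 30 & p$sbp <= 300))
  }
  expect_error(train_bp_model(inst, "boosting"), "unknown algorithm|arg")
  expect_error(predict(rf, inst[, c("subject_id", "timestamp_s")]),
               "schema mismatch")
})

test_that("LOSO evaluation keeps subjects disjoint and reproduces the dummy oracle", {
  inst <- make_toy_instances(n_per_subject = 15, seed = 7)
  ev <- evaluate_loso(inst, algorithm = "decision_tree", seed = 1)
  expect_equal(nrow(ev$folds), 3) # one fold per subject
  expect_setequal(ev$folds$subject_id, unique(inst$subject_id))
  expect_equal(ev$mae_sbp, mean(ev$folds$mae_sbp))

  # dummy fold MAE equals the two-line hand oracle
  for (s in unique(inst$subject_id)) {
    train <- inst[inst$subject_id != s, ]
    test <- inst[inst$subject_id == s, ]
    expect_equal(ev$folds$dummy_mae_sbp[ev$folds$subject_id == s],
                 oracle_dummy_mae(train$sbp, test$sbp))
    expect_equal(ev$folds$dummy_mae_dbp[ev$folds$subject_id == s],
                 oracle_dummy_mae(train$dbp, test$dbp))
  }

  expect_error(evaluate_loso(inst[inst$subject_id == "s1", ]), "2 subjects")
})

test_that("personalized split is chronological at reading granularity with no leakage", {
  inst <- make_toy_instances(n_per_subject = 20, seed = 9)
  one <- inst[inst$subject_id == "s1", ]
  # several cycles per reading
  one <- one[rep(seq_len(nrow(one)), each = 3), ]
  one$timestamp_s <- one$timestamp_s + rep(c(-1, 0, 1), 20)
  ev <- evaluate_personalized(one, algorithm = "decision_tree", seed = 1)
  # 20 readings -> first 14 train, last 6 test
  expect_equal(ev$split$train_readings, 1:14)
  expect_equal(ev$split$test_readings, 15:20)
  expect_lt(ev$split$max_train_time, ev$split$min_test_time)

  # 10 readings -> first 7 train, last 3 test
  ten <- inst[inst$subject_id == "s2", ][1:10, ]
  ten <- ten[rep(seq_len(10), each = 2), ]
  ten$timestamp_s <- ten$timestamp_s + rep(c(0, 1), 10)
  ev10 <- evaluate_personalized(ten, algorithm = "dummy_mean", seed = 1)
  expect_equal(ev10$split$train_readings, 1:7)
  expect_equal(ev10$split$test_readings, 8:10)

  expect_error(evaluate_personalized(one[one$reading_id <= 3, ]),
               "4 distinct readings")
})
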
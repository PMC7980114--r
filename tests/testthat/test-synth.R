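test_that("generators are seed-deterministic and validate their specs", {
  a <- gen_ppg_session(30, hr = 72, noise_sd = 0.05, artifact_rate = 2,
                       seed = 5)
  b <- gen_ppg_session(30, hr = 72, noise_sd = 0.05, artifact_rate = 2,
                       seed = 5)
  expect_identical(a$ppg$samples, b$ppg$samples)
  expect_identical(a$truth, b$truth)
  expect_error(gen_ppg_session(30, hr = 300, seed = 1), "40-180")
  expect_error(gen_ppg_session(30, sbp = 80, dbp = 90, seed = 1), "30 < dbp")
  expect_error(gen_ppg_session(30), "seed")

  s1 <- gen_activity_session(list(list("rest", 4)), seed = 2)
  s2 <- gen_activity_session(list(list("rest", 4)), seed = 2)
  expect_identical(s1$x, s2$x)
  expect_error(gen_activity_session(list(list("flying", 4)), seed = 2),
               "unknown label")

  w1 <- gen_wellbeing_dataset(50, noise = 0, seed = 3)
  w2 <- gen_wellbeing_dataset(50, noise = 0, seed = 3)
  expect_identical(w1$records, w2$records)

  p1 <- gen_profile_dataset(3, seed = 4)
  p2 <- gen_profile_dataset(3, seed = 4)
  expect_identical(p1$features, p2$features)
  expect_error(gen_profile_dataset(0, seed = 4), "n_per_class")
})

test_that("PPG session ground truth matches its construction", {
  # 60 s at 60 bpm, zero noise: exactly 60 beats
  ses <- gen_ppg_session(60, hr = 60, noise_sd = 0, seed = 6)
  expect_equal(ses$truth$n_beats, 60)
  expect_equal(ses$truth$beat_times, 0:59)
  # readings every 30 min of simulated time
  long <- gen_ppg_session(2 * 3600, hr = 70, noise_sd = 0, seed = 6)
  expect_equal(long$readings$timestamp, c(1800, 3600, 5400, 7200))

  # morphology carries SBP: the per-beat upstroke fraction measured on the
  # raw generator output follows the documented affine mapping
  measure_u <- function(sbp) {
    s <- gen_ppg_session(120, hr = 70, sbp = sbp, dbp = 80, noise_sd = 0,
                         seed = 13)
    rate <- s$ppg$rate
    bt <- s$truth$beat_times
    u <- vapply(seq_len(length(bt) - 1L), function(k) {
      i0 <- round(bt[k] * rate) + 1L
      i1 <- round(bt[k + 1L] * rate)
      (which.max(s$ppg$samples[i0:i1]) - 1L) / (i1 - i0 + 1L)
    }, numeric(1))
    mean(u)
  }
  du <- measure_u(110) - measure_u(150)
  expected <- upstroke_fraction_for_sbp(110) - upstroke_fraction_for_sbp(150)
  expect_equal(du, expected, tolerance = 0.02)
})

test_that("activity generator produces the scripted labels and regimes", {
  ses <- gen_activity_session(list(list("rest", 10), list("walking", 20)),
                              seed = 17)
  expect_equal(length(ses$x), 30 * 50)
  expect_setequal(unique(ses$labels), c("rest", "walking"))

  comp <- split_components(ses)
  rest_idx <- which(ses$labels == "rest")
  walk_idx <- which(ses$labels == "walking")
  v_rest <- var(comp$dynamic$x[rest_idx])
  v_walk <- var(comp$dynamic$x[walk_idx])
  expect_gt(v_walk / v_rest, 10)

  # dominant dynamic frequency of walking ~ 2 Hz
  xw <- comp$dynamic$x[walk_idx]
  sp <- abs(fft(xw - mean(xw)))^2
  freqs <- (seq_along(sp) - 1) / length(sp) * 50
  dom <- freqs[freqs > 0.3 & freqs < 25][which.max(sp[freqs > 0.3 & freqs < 25])]
  expect_equal(dom, 2, tolerance = 0.2)
})

test_that("wellbeing generator honors rules, noise rates and imposed correlations", {
  clean <- gen_wellbeing_dataset(300, rule = "temperature <= 25", noise = 0,
                                 seed = 41)
  expect_identical(clean$records$label,
                   ifelse(clean$records$temperature <= 25, "good", "bad"))

  noisy <- gen_wellbeing_dataset(1000, rule = "temperature <= 25",
                                 noise = 0.1, seed = 43)
  flip_rate <- mean(noisy$records$label != noisy$truth$clean_label)
  expect_lt(abs(flip_rate - 0.1), 0.03)

  corr <- gen_wellbeing_dataset(2000, noise = 0,
                                cor_pairs = list(list("humidity",
                                                      "temperature", 0.7)),
                                seed = 47)
  r <- cor(corr$records$humidity, corr$records$temperature)
  expect_gt(r, 0.65)
  expect_lt(r, 0.75)

  expect_error(gen_wellbeing_dataset(10, rule = "altitude > 3", seed = 1),
               "unknown feature")
  expect_error(gen_wellbeing_dataset(10, noise = 0.7, seed = 1), "noise")
})

test_that("profile generator hits its RMSSD targets and balance", {
  ds <- gen_profile_dataset(50, seed = 53)
  expect_equal(as.integer(table(ds$features$label)), rep(50L, 3))
  anx <- ds$features$rmssd[ds$features$label == "anxious"]
  expect_equal(mean(anx), 20, tolerance = 3)

  # zero shift: classes indistinguishable, accuracy near chance
  flat <- gen_profile_dataset(8, shift_scale = 0, seed = 59)
  ev <- evaluate_profile_loso(flat$features, algorithm = "random_forest",
                              seed = 1)
  expect_lt(ev$accuracy, 60)
})
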
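test_that("cycle detection recovers the generated beat train", {
  # constant signal: no oscillation, no cycles
  expect_length(detect_cycles(raw_signal(rep(0.5, 640), 64)), 0)

  # noise-free 60 bpm pulse train over 10 s: 9 or 10 complete cycles of ~1 s
  ses <- gen_ppg_session(10, hr = 60, noise_sd = 0, seed = 3)
  prep <- ppg_preprocess(ses$ppg)
  expect_gte(length(prep$cycles), 9)
  expect_lte(length(prep$cycles), 10)
  durs <- vapply(prep$cycles, function(cc) cc$duration, numeric(1))
  expect_equal(mean(durs), 1.0, tolerance = 1 / 64)

  # 120 bpm train: mean duration 0.5 s within one sample
  ses <- gen_ppg_session(10, hr = 120, noise_sd = 0, seed = 3)
  prep <- ppg_preprocess(ses$ppg)
  durs <- vapply(prep$cycles, function(cc) cc$duration, numeric(1))
  expect_equal(mean(durs), 0.5, tolerance = 1 / 64)
})

test_that("detected cycles are ordered, non-overlapping, valley-to-valley with one interior peak", {
  ses <- gen_ppg_session(30, hr = 75, noise_sd = 0.03, seed = 9)
  prep <- ppg_preprocess(ses$ppg)
  cyc <- prep$cycles
  expect_gt(length(cyc), 10)
  for (cc in cyc) {
    expect_true(cc$valley_start < cc$systolic_peak)
    expect_true(cc$systolic_peak < cc$valley_end)
    expect_gte(cc$duration, 0.25)
    expect_lte(cc$duration, 2.0)
    expect_length(cc$segment, cc$valley_end - cc$valley_start + 1L)
    seg <- cc$segment
    expect_equal(which.max(seg) + cc$valley_start - 1L, cc$systolic_peak)
  }
  starts <- vapply(cyc, function(cc) cc$valley_start, integer(1))
  ends <- vapply(cyc, function(cc) cc$valley_end, integer(1))
  expect_true(all(diff(starts) > 0))
  expect_true(all(starts[-1] >= ends[-length(ends)]))
})

test_that("templates are pointwise location statistics of resampled member cycles", {
  mk <- function(seg) structure(
    list(valley_start = 1L, systolic_peak = which.max(seg),
         valley_end = length(seg), segment = seg,
         duration = length(seg) / 64, rate = 64, start_time = 0),
    class = "cardiac_cycle")

  base <- sin(seq(0, pi, length.out = 40))^2

  # identical cycles: template equals the resampled cycle
  tpl <- build_templates(rep(list(mk(base)), 10), window_size = 10,
                         template_length = 64)
  expect_length(tpl, 1)
  expect_equal(tpl[[1]]$waveform, resample_cycle(mk(base), 64))
  expect_length(tpl[[1]]$waveform, 64)

  # two-cycle window: median of two equals the pointwise mean
  a <- mk(base)
  b <- mk(base * 2 + 0.1)
  tpl2 <- build_templates(list(a, b), window_size = 2, template_length = 10)
  expect_equal(tpl2[[1]]$waveform,
               (resample_cycle(a, 10) + resample_cycle(b, 10)) / 2)

  # empty input
  expect_length(build_templates(list()), 0)
})

test_that("quality scoring flags inverted and noisy cycles and keeps clean ones", {
  mk <- function(seg, dur = 1) structure(
    list(valley_start = 1L, systolic_peak = which.max(seg),
         valley_end = length(seg), segment = seg, duration = dur,
         rate = 64, start_time = 0),
    class = "cardiac_cycle")
  base <- ppg_pulse_shape(seq(0, 0.999, length.out = 64), 120, 80)
  tpl <- build_templates(rep(list(mk(base)), 5), window_size = 5)[[1]]

  # identical: perfect scores
  rep1 <- score_cycle_quality(mk(base), tpl)
  expect_equal(rep1$correlation, 1, tolerance = 1e-9)
  expect_equal(rep1$norm_distance, 0, tolerance = 1e-6)
  expect_true(rep1$keep)

  # sign-inverted: anticorrelated, rejected
  rep2 <- score_cycle_quality(mk(-base), tpl)
  expect_equal(rep2$correlation, -1, tolerance = 1e-9)
  expect_false(rep2$keep)

  # white-noise cycle against a smooth template: rejected on both metrics
  set.seed(5)
  noise_cycle <- mk(rnorm(64))
  nz <- (noise_cycle$segment - mean(noise_cycle$segment)) /
    sqrt(mean((noise_cycle$segment - mean(noise_cycle$segment))^2))
  tz <- (tpl$waveform - mean(tpl$waveform)) /
    sqrt(mean((tpl$waveform - mean(tpl$waveform))^2))
  r_oracle <- mean(nz * tz)
  d_oracle <- sqrt(mean((nz - tz)^2))
  rep3 <- score_cycle_quality(noise_cycle, tpl)
  expect_equal(rep3$correlation, r_oracle, tolerance = 1e-9)
  expect_equal(rep3$norm_distance, d_oracle, tolerance = 1e-9)
  expect_false(rep3$keep)

  # duration deviation gate
  rep4 <- score_cycle_quality(mk(base, dur = 1.5), tpl)
  expect_gt(rep4$duration_deviation, 0.25)
  expect_false(rep4$keep)
})

test_that("screening separates clean from corrupted cycles on a labeled synthetic set", {
  cs <- gen_cycle_set(120, corrupt_frac = 0.25, seed = 8)
  scr <- screen_cycles(cs$cycles)
  expect_gte(mean(scr$kept[!cs$corrupted]), 0.95)
  expect_gte(mean(!scr$kept[cs$corrupted]), 0.90)
})
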
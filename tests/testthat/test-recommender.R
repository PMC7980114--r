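test_that("feature partition separates copied, constructed and independent features", {
  set.seed(19)
  n <- 1000
  m <- rnorm(n)
  rec <- data.frame(m1 = m,
                    copy = m,                       # |r| = 1
                    mix = 0.6 * m + 0.8 * rnorm(n), # population r = 0.6
                    indep = rnorm(n),               # r ~ 0
                    label = sample(c("good", "bad"), n, replace = TRUE))
  part <- partition_features(rec, "m1", threshold = 0.3)
  expect_true("copy" %in% part$correlated)
  expect_true("mix" %in% part$correlated)
  expect_true("indep" %in% part$uncorrelated)
  expect_length(intersect(part$correlated, part$uncorrelated), 0)
  expect_setequal(c(part$modifiable, part$correlated, part$uncorrelated),
                  c("m1", "copy", "mix", "indep"))

  rec$flat <- 1
  expect_warning(p2 <- partition_features(rec, "m1"), "constant")
  expect_true("flat" %in% p2$uncorrelated)
  expect_error(partition_features(rec, "nope"), "outside schema")
  expect_error(partition_features(rec, "m1", threshold = 1.5), "threshold")
})

test_that("correlated-feature models are OLS fits with stored R-squared", {
  set.seed(23)
  n <- 1000
  m <- rnorm(n, 10, 2)
  rec <- data.frame(m1 = m, exact = 2 * m,
                    noisy = 3 + 0.5 * m + rnorm(n, 0, 0.1),
                    label = "bad")
  rec$label[1:10] <- "good"
  part <- fit_correlated_models(rec, partition_features(rec, "m1"))
  expect_equal(unname(part$models$exact$coefficients["m1"]), 2,
               tolerance = 1e-9)
  expect_equal(part$models$exact$intercept, 0, tolerance = 1e-8)
  expect_equal(part$models$exact$r_squared, 1, tolerance = 1e-9)
  expect_gt(unname(part$models$noisy$coefficients["m1"]), 0.45)
  expect_lt(unname(part$models$noisy$coefficients["m1"]), 0.55)

  rec$m2 <- 5 # constant modifiable column -> rank-deficient design
  expect_warning(fit_correlated_models(rec,
                 partition_features(rec, c("m1", "m2"))), "rank-deficient")
})

test_that("propagation preserves residuals and leaves the rest untouched", {
  set.seed(29)
  n <- 200
  m <- rnorm(n, 0, 1)
  rec <- data.frame(m1 = m, f = 2 * m, u = rnorm(n), label = "bad")
  part <- fit_correlated_models(rec, partition_features(rec, "m1"))
  r0 <- rec[5, c("m1", "f", "u")]

  # zero deltas: exact identity
  expect_identical(propagate(r0, c(m1 = 0), part), r0)

  # f = 2 m: a unit shift in m moves f by exactly 2
  r1 <- propagate(r0, c(m1 = 1), part)
  expect_equal(r1$m1, r0$m1 + 1)
  expect_equal(r1$f, r0$f + 2, tolerance = 1e-8)
  expect_identical(r1$u, r0$u) # uncorrelated bit-identical

  expect_error(propagate(r0, c(u = 1), part), "non-modifiable")
})

test_that("objectives compute range-normalized volume and change counts", {
  ranges <- c(a = 10, b = 4)
  expect_equal(unname(objectives(c(a = 0, b = 0), ranges)), c(0, 0))
  expect_equal(unname(objectives(c(a = 5, b = 0), ranges)), c(0.5, 1))
  # additivity over disjoint delta sets
  o_ab <- objectives(c(a = 2, b = 1), ranges)
  o_a <- objectives(c(a = 2, b = 0), ranges)
  o_b <- objectives(c(a = 0, b = 1), ranges)
  expect_equal(unname(o_ab["volume"]), unname(o_a["volume"] + o_b["volume"]))
  expect_error(objectives(c(a = 1), c(a = 0)), "positive")
})

test_that("non-dominated sort matches hand dominance and the brute-force oracle", {
  # single point
  one <- nondominated_sort(matrix(c(1, 1), 1))
  expect_equal(one$rank, 1L)

  # hand-checked 4-point case
  pts <- rbind(c(1, 1), c(2, 2), c(1, 2), c(2, 1))
  s <- nondominated_sort(pts)
  expect_equal(s$rank, c(1L, 3L, 2L, 2L))

  # members of one front never dominate each other; oracle agreement n <= 50
  set.seed(37)
  for (k in 1:8) {
    n <- sample(5:50, 1)
    pts <- cbind(sample(1:10, n, replace = TRUE),
                 sample(1:10, n, replace = TRUE))
    got <- nondominated_sort(pts)
    expect_equal(got$rank, oracle_nds_rank(pts))
    for (fr in unique(got$rank)) {
      idx <- which(got$rank == fr)
      for (i in idx) for (j in idx) {
        if (i != j) {
          expect_false(all(pts[i, ] <= pts[j, ]) && any(pts[i, ] < pts[j, ]))
        }
      }
    }
  }
})

test_that("recommender returns admissible minimal fronts on a 1-D toy", {
  dss <- make_toy_dss("temperature <= 25", n = 400, seed = 31)
  bad_rows <- which(dss$records$label == "bad" &
                    dss$records$temperature > 26.5)
  rec <- dss$records[bad_rows[1], setdiff(names(dss$records), "label")]
  front <- recommend(rec, dss$model, dss$partition, dss$bounds, seed = 7,
                     nsga_config = list(generations = 40))
  expect_s3_class(front, "pareto_front")
  expect_identical(front$status, "ok")
  expect_gt(nrow(front$solutions), 0)

  # every returned modification is admissible under the health model
  deltas <- front$solutions[, paste0("delta_", dss$partition$modifiable),
                            drop = FALSE]
  for (k in seq_len(nrow(deltas))) {
    d <- stats::setNames(as.numeric(deltas[k, ]), dss$partition$modifiable)
    cand <- propagate(rec, d, dss$partition)
    expect_identical(predict(dss$model, cand), "good")
  }

  # single-feature solution near the exhaustive grid optimum
  best1 <- min(front$solutions$volume[front$solutions$n_changed == 1])
  oracle <- axis_grid_oracle(rec, dss$model, "temperature", dss$bounds)
  expect_lt(abs(best1 - oracle), 0.02)

  # a record already predicted good yields an empty front
  good_rows <- which(predict(dss$model, dss$records) == "good")
  grec <- dss$records[good_rows[1], setdiff(names(dss$records), "label")]
  gfront <- recommend(grec, dss$model, dss$partition, dss$bounds, seed = 7)
  expect_identical(gfront$status, "already-good")
  expect_equal(nrow(gfront$solutions), 0)
})
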
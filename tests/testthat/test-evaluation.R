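test_that("confusion matrix counts truth rows against prediction columns", {
  cm <- confusion(c(1, 2, 2, 2), c(1, 1, 2, 2), class_codes = 1:2)
  expect_equal(unname(cm$counts), rbind(c(1L, 1L), c(0L, 2L)))
  expect_equal(sum(cm$counts), 4)
  # perfect prediction is diagonal with row sums = class counts
  truth <- rep(1:3, times = c(5, 2, 3))
  cmp <- confusion(truth, truth, 1:3)
  expect_equal(unname(diag(cmp$counts)), c(5L, 2L, 3L))
  expect_equal(sum(cmp$counts) - sum(diag(cmp$counts)), 0)
  expect_error(confusion(1:3, 1:2), "equal length")
  expect_error(confusion(c(1, 9), c(1, 1), class_codes = 1:2), "outside")
})

test_that("per-class scores match direct substitution of the count ratios", {
  # TP=8 FP=2 FN=1 TN=9 constructed as a 2-class problem
  truth <- c(rep(1, 9), rep(0, 11))
  pred <- c(rep(1, 8), 0, rep(1, 2), rep(0, 9))
  cm <- confusion(pred, truth, 0:1)
  m <- per_class_metrics(cm, 1)
  expect_equal(m$tp, 8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 8 / 9)
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(m$specificity, 9 / 11)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  # perfect prediction gives five ones
  pc <- per_class_metrics(confusion(truth, truth, 0:1), 1)
  expect_equal(unlist(pc[c("accuracy", "precision", "sensitivity",
                           "specificity", "f1")]),
               c(accuracy = 1, precision = 1, sensitivity = 1,
                 specificity = 1, f1 = 1))
  # class absent and never predicted: flagged-0 sensitivity, specificity 1
  cm3 <- confusion(c(1, 1, 2), c(1, 1, 2), class_codes = 1:3)
  m3 <- per_class_metrics(cm3, 3)
  expect_equal(m3$sensitivity, 0)
  expect_true("sensitivity" %in% m3$degenerate)
  expect_equal(m3$specificity, 1)
})

test_that("metric formulas agree with a brute-force recount on random labelings", {
  set.seed(101)
  for (i in 1:300) {
    K <- sample(2:5, 1)
    n <- sample(5:40, 1)
    truth <- sample(seq_len(K), n, replace = TRUE)
    pred <- sample(seq_len(K), n, replace = TRUE)
    cm <- confusion(pred, truth, seq_len(K))
    cls <- sample(seq_len(K), 1)
    got <- unlist(per_class_metrics(cm, cls)[c(
      "accuracy", "precision", "sensitivity", "specificity", "f1")])
    expect_equal(got, oracle_metrics(pred, truth, cls),
                 tolerance = 1e-12)
  }
})

test_that("macro report averages per-class scores without reweighting", {
  truth <- c(1, 1, 1, 2, 2)
  pred <- c(1, 2, 2, 2, 1)
  rep_ <- macro_report(confusion(pred, truth, 1:2))
  pc <- rep_$per_class
  expect_equal(rep_$macro[["f1"]], mean(pc$f1))
  # macro F1 is the mean of per-class F1, not recomputed from macro P/S
  recomputed <- 2 * rep_$macro[["precision"]] * rep_$macro[["sensitivity"]] /
    (rep_$macro[["precision"]] + rep_$macro[["sensitivity"]])
  expect_false(isTRUE(all.equal(rep_$macro[["f1"]], recomputed)))
  # macro scores lie inside the per-class range
  for (mn in c("accuracy", "precision", "sensitivity", "f1"))
    expect_true(rep_$macro[[mn]] >= min(pc[[mn]]) - 1e-12 &&
                rep_$macro[[mn]] <= max(pc[[mn]]) + 1e-12)
  # binary symmetry: sensitivity of one class = specificity of the other
  expect_equal(pc$sensitivity[pc$class == 1],
               pc$specificity[pc$class == 2])
})

test_that("std_eq7 is the n-1 sample standard deviation", {
  expect_equal(std_eq7(c(1, 2, 3)), 1)
  expect_equal(std_eq7(rep(4.2, 6)), 0)
  set.seed(5)
  v <- rnorm(10)
  expect_equal(std_eq7(3 * v), 3 * std_eq7(v))
  expect_equal(std_eq7(v), sqrt(sum((v - mean(v))^2) / 9))
  expect_error(std_eq7(1), "at least 2")
})

test_that("detection delay measures the lag to the matching transition", {
  rec <- generate_recording(
    sim_config(total_duration_s = 120, seed = 21, schedule_block_s = 60))
  truth <- rec$labels
  # identical prediction: zero delay
  d0 <- detection_delay(truth, truth, fs_hz = 40)
  expect_equal(d0$mean_delay_samples, 0)
  # delayed by 4 samples at 40 Hz: 100 ms
  shifted <- shift_labels(rec, 4)$labels
  d4 <- detection_delay(shifted, truth, fs_hz = 40)
  expect_equal(d4$mean_delay_samples, 4)
  expect_equal(d4$mean_delay_ms, 100)
  # unit conversion at a different rate
  d10 <- detection_delay(c(rep(1, 30), rep(2, 30)),
                         c(rep(1, 20), rep(2, 40)), fs_hz = 50)
  expect_equal(d10$mean_delay_samples, 10)
  expect_equal(d10$mean_delay_ms, 200)
  expect_error(detection_delay(truth, rep(1, length(truth)), 40),
               "no label transitions")
})

test_that("segment CV trains inside each fold and aggregates with eq-7 spread", {
  rec <- short_rec()
  spec <- classifier_spec("oracle")
  cv <- segment_cv(rec, spec, n_segments = 4, mode = "raw")
  expect_length(cv$fold_reports, 4)
  # the oracle stub is perfect: means 1, spread 0
  expect_equal(unname(cv$mean_report[["f1"]]), 1)
  expect_equal(unname(cv$std_report[["overall_accuracy"]]), 0)
  # a real (fast) classifier: scores bounded by fold extremes
  cv2 <- segment_cv(rec, classifier_spec("dt"), n_segments = 4)
  f1s <- vapply(cv2$fold_reports, function(r) r$macro[["f1"]], 0)
  expect_true(cv2$mean_report[["f1"]] >= min(f1s) - 1e-12)
  expect_true(cv2$mean_report[["f1"]] <= max(f1s) + 1e-12)
  expect_equal(unname(cv2$std_report[["f1"]]), std_eq7(f1s))
  expect_error(segment_cv(rec, spec, n_segments = 7), "divisible")
})

test_that("folds lacking a class are skipped with a warning", {
  rec <- short_rec()
  # overwrite the first quarter's labels so segment 1 lacks classes
  rec$labels[1:2400] <- 2L
  expect_warning(
    cv <- segment_cv(rec, classifier_spec("oracle"), n_segments = 4),
    "skipped")
  expect_equal(cv$skipped_folds, 1L)
  expect_length(cv$fold_reports, 3)
})

test_that("sensor ablation re-derives features per subset", {
  rec <- short_rec()
  tab <- ablate_sensors(rec, classifier_spec("oracle"),
                        protocol = "cv", mode = "raw", n_segments = 2)
  expect_equal(nrow(tab), 15)
  expect_equal(tab$combination[1], "CF")
  expect_equal(tab$combination[15], "CF, ACC, GYRO, SG")
  expect_true(all(tab$f1 == 1))
  # all 15 subsets of 4 groups are enumerated
  expect_length(sensor_combinations(), 15)
  expect_error(ablate_sensors(rec, classifier_spec("oracle"),
                              combinations = list()), "non-empty")
})

test_that("the FOG protocol splits chronologically at 60% and scores class 1", {
  cfg <- sim_config(total_duration_s = 240, seed = 31,
                    fog = fog_config(n_episodes = 6,
                                     episode_duration_s = c(2, 6),
                                     target_fraction = 0.1))
  rec <- generate_fog_recording(cfg)
  rep_ <- fog_protocol(rec, classifier_spec("oracle", n_classes = 2),
                       mode = "raw")
  expect_equal(rep_$split_index, floor(0.6 * nrow(rec$data)))
  expect_equal(unname(rep_$positive[["f1"]]), 1)
  expect_equal(unname(rep_$positive[["sensitivity"]]), 1)

  # all-negative prediction arithmetic on the test part
  T <- nrow(rec$data)
  test_idx <- (rep_$split_index + 1):T
  cm <- confusion(rep(0, length(test_idx)), rec$labels[test_idx], 0:1)
  m <- per_class_metrics(cm, 1)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$accuracy, mean(rec$labels[test_idx] == 0))

  # a part missing one class errors
  rec2 <- rec
  rec2$labels[(rep_$split_index + 1):T] <- 0L
  expect_error(fog_protocol(rec2, classifier_spec("oracle", n_classes = 2),
                            mode = "raw"), "missing from the test")
})
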
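test_that("reference activity distributions are valid fractions", {
  m <- default_table2_distribution("mean")
  expect_equal(unname(m), c(9.5, 58.8, 6.8, 13.6, 11.3) / 100)
  s1 <- default_table2_distribution(1)
  expect_equal(unname(s1), c(12.2, 51.4, 9.6, 14.4, 12.4) / 100)
  # every printed row sums to 1 within printed rounding (0.3%)
  for (sel in c(1:5, "mean"))
    expect_lt(abs(sum(default_table2_distribution(sel)) - 1), 0.003)
  expect_error(default_table2_distribution(7), "1..5")
})

test_that("generated recordings have the configured shape and are seed-reproducible", {
  cfg <- sim_config(total_duration_s = 90, seed = 17,
                    schedule_block_s = 45)
  rec <- generate_recording(cfg)
  expect_equal(nrow(rec$data), 90 * 40)
  expect_equal(ncol(rec$data), 20)
  expect_true(all(rec$labels %in% 1:5))
  rec2 <- generate_recording(cfg)
  expect_identical(rec$data, rec2$data)
  expect_identical(rec$labels, rec2$labels)
  # a different seed changes the signal
  rec3 <- generate_recording(sim_config(total_duration_s = 90, seed = 18,
                                        schedule_block_s = 45))
  expect_false(identical(rec$data, rec3$data))
  # the generator leaves the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_recording(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("realized activity fractions track the target distribution", {
  cfg <- sim_config(total_duration_s = 600, seed = 23)
  rec <- generate_recording(cfg)
  frac <- tabulate(rec$labels, 5) / length(rec$labels)
  target <- unname(cfg$target_distribution / sum(cfg$target_distribution))
  # within one scheduling round-off of the target per class
  expect_true(all(abs(frac - target) < 0.01))
  # every scheduling block contains all five activities (600 s with
  # 180 s nominal blocks realizes three 200 s blocks)
  for (s in slice_segments(rec, 3))
    expect_setequal(unique(s$labels), 1:5)
})

test_that("explicit schedules are honoured and unknown activities rejected", {
  sched <- data.frame(activity = c("walking", "running", "walking"),
                      duration_s = c(20, 10, 30))
  rec <- generate_recording(
    sim_config(total_duration_s = 60, activity_schedule = sched,
               seed = 3))
  expect_equal(nrow(rec$data), 2400)
  expect_equal(unique(rec$labels), c(2L, 3L))
  expect_equal(sum(rec$labels == 3), 400)
  expect_error(
    sim_config(total_duration_s = 10,
               activity_schedule = data.frame(activity = "flying",
                                              duration_s = 10)),
    "unknown activity")
  expect_error(
    sim_config(target_distribution = c(0.5, 0.2, 0.1, 0.1, 0.05)),
    "sum to 1")
})

test_that("profile constraints mirror the gait frequency band", {
  expect_error(activity_profile("walking", 12), "0.5-10")
  expect_error(activity_profile("walking", 0.2), "0.5-10")
  expect_silent(activity_profile("resting", 0))
  p <- default_profiles()
  expect_equal(p$resting$stride_freq_hz, 0)
  expect_lt(p$resting$acc_amp, 0.1)
  # ascent and descent differ in frequency and asymmetry sign
  expect_true(p$ascending_stairs$stride_freq_hz !=
                p$descending_stairs$stride_freq_hz)
  expect_true(p$ascending_stairs$asymmetry *
                p$descending_stairs$asymmetry < 0)
})

test_that("FOG recordings carry disjoint labelled episodes near the target fraction", {
  cfg <- sim_config(total_duration_s = 1440, seed = 41,
                    fog = fog_config())
  rec <- generate_fog_recording(cfg)
  expect_equal(nrow(rec$data), 57600)
  expect_equal(rec$label_mode, "fog_binary")
  reg <- attr(rec, "fog_episodes")
  expect_equal(nrow(reg), 13)
  # disjoint and ordered
  expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
  # durations within the configured range (1-20 s band)
  dur_s <- (reg$end - reg$start + 1) / 40
  expect_true(all(dur_s >= 1 & dur_s <= 20))
  # achieved fraction within one percentage point of the target
  expect_lt(abs(mean(rec$labels) - 0.082), 0.01)
  # labels flip exactly at the registry boundaries
  lab <- rec$labels
  for (r in seq_len(nrow(reg))) {
    expect_true(all(lab[reg$start[r]:reg$end[r]] == 1))
    expect_equal(lab[reg$start[r] - 1], 0L)
    expect_equal(lab[reg$end[r] + 1], 0L)
  }
  # determinism
  rec2 <- generate_fog_recording(cfg)
  expect_identical(rec$data, rec2$data)
})

test_that("FOG scenarios shape the sensor channels as designed", {
  cfg <- sim_config(total_duration_s = 1440, seed = 41,
                    fog = fog_config())
  rec <- generate_fog_recording(cfg)
  reg <- attr(rec, "fog_episodes")
  sg <- rowMeans(abs(rec$data[, c("STRAIN_GAUGE_LEFT_X",
                                  "STRAIN_GAUGE_RIGHT_X")]))
  acc <- rowMeans(abs(rec$data[, sensor_layout()$channel[7:12]]))
  rest_bg <- which(rec$labels == 0)
  for (r in seq_len(nrow(reg))) {
    idx <- reg$start[r]:reg$end[r]
    # strain gauge trembles in every episode
    expect_gt(mean(sg[idx]), mean(sg[rest_bg]))
    if (reg$scenario[r] == "gait_initiation") {
      # IMU stays quiet relative to the walking background
      expect_lt(mean(acc[idx]), mean(acc))
    }
  }
})

test_that("zero-fraction FOG config yields all-negative labels", {
  cfg <- sim_config(total_duration_s = 120, seed = 2,
                    fog = fog_config(n_episodes = 0, target_fraction = 0))
  rec <- generate_fog_recording(cfg)
  expect_true(all(rec$labels == 0))
  # infeasible target errors before synthesis
  expect_error(
    generate_fog_recording(
      sim_config(total_duration_s = 120, seed = 2,
                 fog = fog_config(n_episodes = 2,
                                  episode_duration_s = c(1, 2),
                                  target_fraction = 0.5))),
    "not reachable")
})

test_that("label shifting pads edges and inverts away from them", {
  rec <- tiny_recording(30)
  expect_identical(shift_labels(rec, 0)$labels, rec$labels)
  s4 <- shift_labels(rec, 4)
  expect_equal(s4$labels[1:4], rep(rec$labels[1], 4))
  expect_equal(s4$labels[5:30], rec$labels[1:26])
  back <- shift_labels(s4, -4)
  expect_equal(back$labels[5:26], rec$labels[5:26])
  expect_error(shift_labels(rec, 30), "smaller than")
})
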
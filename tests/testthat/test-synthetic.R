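test_that("a flat profile yields constant truth HR and ~750 ms beats", {
  p <- truth_profile(duration_s = 1200, base_hr_awake_bpm = 80,
                     base_hr_sleep_bpm = 79.999, sleep_onset_s = 1e6,
                     wake_s = 2e6, rsa_amplitude_bpm = 0,
                     hrv_wander_sd_bpm = 0, n_activity_bouts = 0, seed = 5)
  tr <- gen_truth_hr(p)
  expect_equal(tr$hr$bpm, rep(80, 1200), tolerance = 1e-4)
  # beats: 60000/80 = 750 ms up to the 2% multiplicative jitter
  expect_equal(median(tr$rr$rr_ms), 750, tolerance = 0.01)
  expect_lt(max(abs(log(tr$rr$rr_ms / 750))), 5 * 0.02 + 1e-6)
})

test_that("beat count matches the integral of the HR profile within 1%", {
  p <- truth_profile(duration_s = 7200, sleep_onset_s = 3600, wake_s = 7000,
                     n_activity_bouts = 3, seed = 21)
  tr <- gen_truth_hr(p)
  expected_beats <- sum(tr$hr$bpm) / 60
  expect_lt(abs(nrow(tr$rr) - expected_beats) / expected_beats, 0.01)
})

test_that("truth HR is lower during sleep than wake for the default profile", {
  p <- truth_profile(seed = 31)
  tr <- gen_truth_hr(p)
  asleep <- tr$hr$t >= p$sleep_onset_s & tr$hr$t < p$wake_s
  expect_lt(mean(tr$hr$bpm[asleep]), mean(tr$hr$bpm[!asleep]))
})

test_that("bout windows have higher movement magnitude; zero-bout stays at floor", {
  p <- truth_profile(duration_s = 7200, sleep_onset_s = 1e6, wake_s = 2e6,
                     n_activity_bouts = 4, bout_duration_range_s = c(300, 600),
                     seed = 41)
  mov <- accel_magnitude(gen_accel(p))
  b <- ambuvalid:::bout_windows(p)
  in_bout <- rep(FALSE, nrow(mov))
  for (i in seq_len(nrow(b)))
    in_bout <- in_bout | (mov$t >= b$start_s[i] & mov$t < b$start_s[i] + b$duration_s[i])
  expect_gt(mean(mov$intensity_g[in_bout]), 3 * mean(mov$intensity_g[!in_bout]))

  p0 <- truth_profile(duration_s = 3600, sleep_onset_s = 1e6, wake_s = 2e6,
                      n_activity_bouts = 0, rest_acc_modulation_sd = 0,
                      wake_fidget_g = 0, seed = 42)
  mov0 <- accel_magnitude(gen_accel(p0))
  # rest floor: mean magnitude ~ 2.26 * rest noise SD
  expect_equal(mean(mov0$intensity_g), 2.26 * p0$rest_acc_noise_g, tolerance = 0.05)
})

test_that("an all-zero error model reproduces the truth exactly", {
  p <- truth_profile(duration_s = 1800, sleep_onset_s = 1e6, wake_s = 2e6, seed = 7)
  tr <- gen_truth_hr(p)
  w <- corrupt_wearable(tr$hr, model = wearable_error_model(), seed = 1)
  expect_identical(w$t, tr$hr$t)
  expect_equal(w$bpm, tr$hr$bpm, tolerance = 1e-12)
})

test_that("a pure clock offset delays the truth exactly", {
  p <- truth_profile(duration_s = 1800, sleep_onset_s = 1e6, wake_s = 2e6, seed = 8)
  tr <- gen_truth_hr(p)
  w <- corrupt_wearable(tr$hr, model = wearable_error_model(clock_offset_s = 30),
                        seed = 1)
  expect_equal(w$t[1], 30)
  expect_equal(w$bpm, tr$hr$bpm[seq_len(nrow(w))], tolerance = 1e-12)
})

test_that("realized dropout matches its probability within binomial bounds", {
  p <- truth_profile(duration_s = 14400, sleep_onset_s = 1e6, wake_s = 2e6, seed = 9)
  tr <- gen_truth_hr(p)
  w <- corrupt_wearable(tr$hr,
                        model = wearable_error_model(dropout_prob_rest = 0.025,
                                                     zero_fill = TRUE),
                        seed = 2)
  n <- nrow(w)
  frac <- mean(w$bpm == 0)
  band <- 2.576 * sqrt(0.025 * 0.975 / n)   # binomial 99% bounds
  expect_lt(abs(frac - 0.025), band)
})

test_that("constant-fill policy repeats the last known heartbeat", {
  p <- truth_profile(duration_s = 1200, sleep_onset_s = 1e6, wake_s = 2e6, seed = 10)
  tr <- gen_truth_hr(p)
  w <- corrupt_wearable(tr$hr,
                        model = wearable_error_model(dropout_prob_rest = 0.2,
                                                     constant_fill_bpm = 70),
                        seed = 3)
  expect_false(anyNA(w$bpm))
  # dropped rows equal the previous surviving value or the 70 BPM constant
  d <- which(abs(w$bpm - tr$hr$bpm) > 1e-9)
  expect_true(all(w$bpm[d] == 70 | w$bpm[d] == w$bpm[pmax(d - 1, 1)]))
})

test_that("the sample-rate defect thins the stream to one per minute", {
  p <- truth_profile(duration_s = 14400, sleep_onset_s = 1e6, wake_s = 2e6, seed = 11)
  tr <- gen_truth_hr(p)
  bug <- list(start_s = 7200, degraded_rate_hz = 1 / 60)
  w <- corrupt_wearable(tr$hr, model = wearable_error_model(samplerate_bug = bug),
                        seed = 4)
  dt_before <- diff(w$t[w$t < 7200])
  dt_after <- diff(w$t[w$t >= 7200])
  expect_true(all(dt_before == 1))
  expect_true(all(dt_after == 60))
})

test_that("gen_cohort is byte-identical under a fixed seed and ledgers everyone", {
  sc <- cohort_scenario(duration_s = 3700)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  l1 <- gen_cohort(2, sc, seed = 77, out_dir = d1)
  l2 <- gen_cohort(2, sc, seed = 77, out_dir = d2)
  expect_equal(nrow(l1), 2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
  expect_error(gen_cohort(2, sc, seed = 77, out_dir = d1), "overwrite")
})

test_that("cohort metadata follows the scenario distributions", {
  sc <- cohort_scenario(duration_s = 3700)
  d <- withr::local_tempdir()
  gen_cohort(30, sc, seed = 5, out_dir = d, overwrite = TRUE)
  metas <- lapply(list.dirs(d, recursive = FALSE), function(pd)
    read_meta(file.path(pd, "meta.yaml")))
  ages <- vapply(metas, `[[`, 0, "age_years")
  expect_lt(abs(mean(ages) - 13.2), 1.5)   # target mean 13.2, n = 30
  expect_true(all(ages >= 6 & ages <= 18))
  expect_true(all(vapply(metas, `[[`, "", "indication") %in%
                    c("CHD", "arrhythmia", "symptoms")))
})
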
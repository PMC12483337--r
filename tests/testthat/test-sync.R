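test_that("16-beat moving-average HR matches hand-computed values", {
  # constant 1000 ms intervals -> 60 BPM at the 16th beat
  rr <- rr_series(cumsum(rep(1, 16)), rep(1000, 16))
  h <- hr_from_rr(rr)
  expect_equal(nrow(h), 1)
  expect_equal(h$bpm, 60)
  expect_equal(h$t, rr$beat_time[16])

  expect_equal(hr_from_rr(rr_series(cumsum(rep(0.5, 16)), rep(500, 16)))$bpm, 120)

  # 8 beats of 600 ms then 8 of 1000 ms: window mean 800 ms -> 75 BPM
  rr3 <- rr_series(cumsum(c(rep(0.6, 8), rep(1, 8))), c(rep(600, 8), rep(1000, 8)))
  expect_equal(hr_from_rr(rr3)$bpm, 75)
})

test_that("moving-average HR equals a brute-force window mean at every beat", {
  set.seed(101)
  n <- 400
  rrms <- runif(n, 350, 1300)
  rr <- rr_series(cumsum(rrms) / 1000, rrms)
  h <- hr_from_rr(rr, window_beats = 16)
  brute <- vapply(16:n, function(i) 60000 / mean(rrms[(i - 15):i]), 0)
  expect_lt(max(abs(h$bpm - brute)), 1e-9)
  # shorter-than-window series warns and returns empty
  expect_warning(h0 <- hr_from_rr(rr_series(1:5, rep(800, 5))), "shorter")
  expect_equal(nrow(h0), 0)
})

test_that("offset estimation recovers pure shifts and is antisymmetric", {
  x <- make_hr(1200)
  expect_identical(estimate_offset(x, x)$offset_s, 0L)
  expect_equal(estimate_offset(x, x)$peak_correlation, 1.0, tolerance = 1e-12)

  shifted <- hr_series(x$t + 30, x$bpm)   # same values, clock 30 s ahead
  s <- estimate_offset(x, shifted)
  expect_identical(s$offset_s, 30L)
  expect_identical(estimate_offset(shifted, x)$offset_s, -30L)
})

test_that("offset estimation rejects degenerate input", {
  flat <- hr_series(0:999, rep(70, 1000))
  x <- make_hr(1000)
  expect_error(estimate_offset(x, flat), "constant")
  short <- make_hr(200)
  expect_error(estimate_offset(short, short), "overlap")
})

test_that("resampling passes values through on identical grids and is exact on ramps", {
  crit <- make_hr(600)
  p <- resample_to_criterion(crit, crit, 0)
  expect_equal(p$wearable_bpm, crit$bpm)
  expect_true(all(p$missing_cause == "none"))

  # wearable at 0.5 Hz, criterion at 1 Hz, linear signal: interpolation exact
  ramp <- function(t) 60 + t / 10
  wear <- hr_series(seq(0, 598, by = 2), ramp(seq(0, 598, by = 2)))
  crit2 <- hr_series(0:598, ramp(0:598))
  p2 <- resample_to_criterion(wear, crit2, 0)
  expect_equal(p2$wearable_bpm, crit2$bpm, tolerance = 1e-12)
})

test_that("long wearable gaps are not bridged and zeros are missing", {
  keep <- c(0:99, 220:599)                      # 120 s hole
  wear <- hr_series(keep, 80 + keep / 100)
  crit <- make_hr(600)
  p <- resample_to_criterion(wear, crit, 0, max_bridge_gap_s = 60)
  inside <- p$t > 99 & p$t < 220
  expect_true(all(p$missing_cause[inside] == "underdetected"))
  expect_equal(sum(inside), 120)
  expect_true(all(p$missing_cause[!inside] == "none"))

  # zero-valued wearable samples are excluded before interpolation
  bpm <- rep(80, 600); bpm[300] <- 0
  p3 <- resample_to_criterion(hr_series(0:599, bpm), crit, 0)
  expect_equal(p3$wearable_bpm[p3$t == 300], 80)  # bridged from neighbours
})

test_that("interpolated values always lie between their bracketing samples", {
  set.seed(55)
  wt <- sort(runif(200, 0, 600))
  wear <- hr_series(wt, runif(200, 50, 150))
  crit <- make_hr(580, t0 = 5)
  p <- resample_to_criterion(wear, crit, 0, max_bridge_gap_s = 1e6)
  ok <- p$missing_cause == "none"
  for (i in which(ok)) {
    j <- findInterval(p$t[i], wt)
    lo_v <- min(wear$bpm[j], wear$bpm[min(j + 1, 200)])
    hi_v <- max(wear$bpm[j], wear$bpm[min(j + 1, 200)])
    expect_gte(p$wearable_bpm[i], lo_v - 1e-12)
    expect_lte(p$wearable_bpm[i], hi_v + 1e-12)
  }
})

test_that("missingness percentages and the sample-rate anomaly flag", {
  crit <- make_hr(3600)
  wear <- make_hr(3600)
  # poison 36 criterion rows -> 1.0% erroneous
  crit$bpm[100:135] <- NA
  suppressWarnings(p <- resample_to_criterion(wear, hr_series(crit$t, crit$bpm), 0))
  m <- classify_missing(p, wear)
  expect_equal(m$pct_erroneous, 1.0)
  expect_equal(m$pct_underdetected, 0)
  expect_false(m$samplerate_anomaly)

  # a >= 1 h run of 60 s intervals trips the anomaly flag
  t_slow <- c(0:999, seq(1060, 1060 + 70 * 60, by = 60))
  wear2 <- hr_series(t_slow, 80 + sin(t_slow / 40))
  p2 <- resample_to_criterion(wear2, make_hr(5260), 0)
  m2 <- classify_missing(p2, wear2)
  expect_true(m2$samplerate_anomaly)
  expect_gt(m2$pct_underdetected, 50)  # absent samples dominate
})

test_that("erroneous rows never enter downstream statistics", {
  set.seed(66)
  crit <- 80 + rnorm(500, 0, 5)
  wear <- crit + rnorm(500, -1, 3)
  p_clean <- make_paired(crit[1:450], wear[1:450])
  # append poisoned rows: criterion missing, absurd sentinel wearable values
  p_poison <- rbind(p_clean,
                    make_paired(rep(NA_real_, 50), rep(999, 50),
                                cause = rep("erroneous", 50)))
  class(p_poison) <- class(p_clean)
  expect_equal(accuracy_within(p_poison), accuracy_within(p_clean))
  expect_equal(mae(p_poison), mae(p_clean))
  expect_equal(lin_ccc(p_poison), lin_ccc(p_clean))
  expect_equal(bland_altman(p_poison)$bias, bland_altman(p_clean)$bias)
})

test_that("constant-fill runs are masked", {
  bpm <- c(70 + sin(1:100), rep(70, 60), 70 + sin(1:100))
  x <- hr_series(seq_along(bpm) - 1, bpm)
  mask <- detect_constant_fill(x, fill_bpm = 70, min_run_s = 30)
  expect_equal(sum(mask), 60)
  runs <- attr(mask, "runs")
  expect_true(runs$is_fill_value[1])
  noisy <- hr_series(0:199, 80 + rnorm(200))
  expect_equal(sum(detect_constant_fill(noisy)), 0)
})

test_that("masked constant-fill fraction tracks the injected dropout fraction", {
  p <- truth_profile(duration_s = 14400, sleep_onset_s = 1e6, wake_s = 2e6,
                     seed = 12)
  tr <- gen_truth_hr(p)
  # heavy burst-like dropout: almost all samples sit in runs longer than the
  # 30 s mask threshold, so the masked fraction approaches the dropout fraction
  w <- corrupt_wearable(tr$hr,
                        model = wearable_error_model(dropout_prob_rest = 0.995,
                                                     constant_fill_bpm = 70),
                        seed = 6)
  mask <- detect_constant_fill(w, min_run_s = 30)
  expect_lt(abs(mean(mask) - 0.995), 0.0995)
})
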
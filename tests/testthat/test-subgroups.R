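test_that("sleep/wake labelling excludes the guard window around transitions", {
  p <- make_paired(rep(80, 200), rep(80, 200))
  p$t <- seq(30000, 40000, length.out = 200)
  diary <- validate_diary(data.frame(sleep_onset_s = 36000, wake_s = 77400,
                                     notes = ""))
  lab <- split_sleep_wake(p, diary, guard_min = 60)
  excl <- p$t >= 34200 & p$t < 37800
  expect_true(all(lab[excl] == "excluded"))
  expect_true(all(lab[p$t < 34200] == "wake"))
  expect_true(all(lab[p$t >= 37800] == "sleep"))
  expect_message(expect_null(split_sleep_wake(p, NULL)), "skipped")
})

test_that("median-HR split sends ties low and halves a uniform grid", {
  p <- make_paired(rep(75, 10), rep(75, 10))
  expect_true(all(split_hr_median(p) == "low"))
  p2 <- make_paired(1:100 + 50, 1:100 + 50)
  expect_equal(unname(table(split_hr_median(p2))), c(50L, 50L),
               ignore_attr = TRUE)
})

test_that("period split halves a 24 h recording and skips short ones", {
  p <- make_paired(rep(80, 100), rep(80, 100))
  p$t <- seq(0, 86400, length.out = 100)
  lab <- split_period(p)
  expect_equal(sum(lab == "first"), 50)
  p_short <- make_paired(rep(80, 100), rep(80, 100))
  p_short$t <- seq(0, 13 * 3600, length.out = 100)
  expect_message(expect_null(split_period(p_short)), "skipped")
})

test_that("within-participant schemes never dispatch to independent-sample tests", {
  set.seed(91)
  df <- data.frame(participant = rep(sprintf("P%02d", 1:20), each = 2),
                   group = rep(c("wake", "sleep"), 20),
                   value = 85 + rnorm(40, 0, 5))
  r <- subgroup_test(df, "within_participant", scheme = "time_of_day")
  expect_true(r$test_used %in% c("paired-t", "Wilcoxon", "degenerate"))
  expect_false(r$test_used %in% c("t", "Mann-Whitney", "ANOVA", "Kruskal-Wallis"))
  expect_error(subgroup_test(df, "within_participant_typo"))
})

test_that("identical groups give p = 1 and a degenerate label", {
  df <- data.frame(participant = sprintf("P%02d", 1:12),
                   group = rep(c("a", "b"), each = 6), value = 90)
  r <- subgroup_test(df, "between_participant")
  expect_equal(r$p_value, 1)
  expect_equal(r$test_used, "degenerate")
  dfw <- data.frame(participant = rep(sprintf("P%02d", 1:6), each = 2),
                    group = rep(c("x", "y"), 6), value = 90)
  expect_equal(subgroup_test(dfw, "within_participant")$p_value, 1)
})

test_that("small groups error with the scheme named", {
  df <- data.frame(participant = sprintf("P%02d", 1:5),
                   group = c("a", "a", "a", "a", "b"), value = rnorm(5))
  expect_error(subgroup_test(df, "between_participant", scheme = "bmi"),
               "n = 1")
})

test_that("three groups dispatch to ANOVA or Kruskal-Wallis", {
  set.seed(92)
  df <- data.frame(participant = sprintf("P%02d", 1:30),
                   group = rep(c("CHD", "arrhythmia", "symptoms"), each = 10),
                   value = 85 + rnorm(30, 0, 4))
  r <- subgroup_test(df, "between_participant", scheme = "diagnosis")
  expect_true(r$test_used %in% c("ANOVA", "Kruskal-Wallis"))
  expect_equal(nrow(r$groups), 3)
})

test_that("a within-participant shift of 5 accuracy points is detected", {
  set.seed(93)
  rejected <- 0
  for (i in 1:50) {
    base <- 85 + rnorm(30, 0, 5)
    df <- data.frame(participant = rep(sprintf("P%02d", 1:30), each = 2),
                     group = rep(c("wake", "sleep"), 30),
                     value = as.vector(rbind(base, base + 5 + rnorm(30, 0, 3))))
    r <- subgroup_test(df, "within_participant")
    rejected <- rejected + (r$p_value < 0.05)
  }
  expect_gt(rejected / 50, 0.9)
})

test_that("quantile accuracy table averages participants and excludes flagged ids", {
  bins <- expand.grid(participant = c("P01", "P02", "P03"), quantile = 1:4)
  bins$accuracy_pct <- c(90, 92, 94, 85, 87, 89, 80, 82, 84, 70, 72, 74)
  tab <- quantile_accuracy_table(bins, exclude = "P03")
  expect_equal(tab$n, rep(2L, 4))
  expect_equal(tab$mean_accuracy_pct[1], mean(c(90, 92)))
  # single participant: SD not available
  tab1 <- quantile_accuracy_table(bins[bins$participant == "P01", ])
  expect_true(all(is.na(tab1$sd_accuracy_pct)))
})

test_that("interaction regression recovers group-specific coupling and rejects collinearity", {
  set.seed(94)
  mk_df <- function(slope_young, slope_old) {
    g <- rep(c(0.01, 0.05, 0.15, 0.3), times = 30)
    age <- rep(rep(c("<=12y", ">12y"), each = 4), 15)
    slope <- ifelse(age == "<=12y", slope_young, slope_old)
    data.frame(participant = rep(sprintf("P%02d", 1:30), each = 4),
               age_group = age, movement_g = g,
               accuracy_pct = 95 - slope * g + rnorm(120, 0, 2))
  }
  # identical coupling: interaction should rarely look significant
  r0 <- accel_accuracy_regression(mk_df(60, 60))
  expect_s3_class(r0, "accel_regression")
  # coupling only in the younger group: clearly detected
  r1 <- accel_accuracy_regression(mk_df(120, 0))
  expect_lt(r1$interaction_p, 0.01)

  bad <- mk_df(60, 60); bad$movement_g <- as.numeric(bad$age_group == ">12y")
  expect_error(accel_accuracy_regression(bad), "collinear")
})

test_that("null interaction is not significant in most replicates", {
  set.seed(95)
  hits <- 0; n_rep <- 50
  for (i in 1:n_rep) {
    g <- rep(c(0.01, 0.05, 0.15, 0.3), times = 30)
    age <- rep(rep(c("<=12y", ">12y"), each = 4), 15)
    df <- data.frame(participant = rep(sprintf("P%02d", 1:30), each = 4),
                     age_group = age, movement_g = g,
                     accuracy_pct = 95 - 60 * g + rnorm(120, 0, 3))
    hits <- hits + (accel_accuracy_regression(df)$interaction_p < 0.05)
  }
  expect_lte(hits / n_rep, 0.14)   # nominal 5%, generous Monte-Carlo margin
})

test_that("comfort summary medians, pairing and the all-shifted case", {
  set.seed(96)
  mk_q <- function(pid, device, mu) {
    out <- data.frame(participant = pid, device = device, wear_time_h = 24)
    out[paste0("q", 1:6)] <- as.list(pmin(pmax(round(mu + rnorm(6, 0, 0.5)), 1), 5))
    out
  }
  rows <- do.call(rbind, c(
    lapply(1:20, function(i) mk_q(sprintf("P%02d", i), "criterion", 2.6)),
    lapply(1:20, function(i) mk_q(sprintf("P%02d", i), "wearable_wrist", 3.8))))
  cs <- comfort_summary(rows)
  expect_true(all(cs$device_summary$median >= 1 & cs$device_summary$median <= 5))
  expect_gt(cs$device_summary$median[cs$device_summary$device == "wearable_wrist"],
            cs$device_summary$median[cs$device_summary$device == "criterion"])
  expect_lt(cs$tests$wearable_wrist$p_value, 0.01)

  # +1 everywhere: all-positive paired differences, decisive at modest n
  shift <- rows
  shift[shift$device == "wearable_wrist", paste0("q", 1:6)] <-
    pmin(shift[shift$device == "criterion", paste0("q", 1:6)] + 1, 5)
  cs2 <- comfort_summary(shift)
  expect_lt(cs2$tests$wearable_wrist$p_value, 0.001)
  expect_equal(cs2$tests$wearable_wrist$median_difference, 1, tolerance = 0.2)
})
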
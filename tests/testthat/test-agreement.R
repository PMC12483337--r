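test_that("within-10% accuracy follows the rule on hand-evaluated pairs", {
  p <- make_paired(c(100, 100, 50, 50), c(108, 89, 54, 56))
  # |8|/100 <= .1 yes; |11|/100 no; |4|/50 <= .1 yes; |6|/50 no -> 50%
  expect_equal(accuracy_within(p), 50)
  ident <- make_paired(70:90, 70:90)
  expect_equal(accuracy_within(ident), 100)
  expect_equal(accuracy_within(make_paired(70:90, 1.12 * (70:90))), 0)
})

test_that("MAE and MAPE on hand-computed pairs and the scale-free property", {
  p <- make_paired(c(100, 200), c(90, 190))
  expect_equal(mae(p), 10)
  expect_equal(mape(p), (10 / 100 + 10 / 200) / 2 * 100)  # 7.5
  prop <- make_paired(70:120, 1.05 * (70:120))
  expect_equal(mape(prop), 5, tolerance = 1e-12)
  expect_equal(mae(make_paired(80:99, 80:99)), 0)
  expect_equal(mape(make_paired(80:99, 80:99)), 0)
})

test_that("agreement metrics are scale- and order-invariant as expected", {
  set.seed(81)
  c0 <- 60 + rexp(300, 1 / 20)
  w0 <- c0 + rnorm(300, -1, 4)
  p <- make_paired(c0, w0)
  lam <- 2.5
  p_scaled <- make_paired(lam * c0, lam * w0)
  expect_equal(accuracy_within(p_scaled), accuracy_within(p))
  expect_equal(mae(p_scaled), lam * mae(p))
  expect_equal(mape(p_scaled), mape(p))
  perm <- sample(300)
  p_perm <- make_paired(c0[perm], w0[perm])
  expect_equal(accuracy_within(p_perm), accuracy_within(p))
  expect_equal(lin_ccc(p_perm), lin_ccc(p), tolerance = 1e-12)
  expect_equal(bland_altman(p_perm)$loa_high, bland_altman(p)$loa_high)
})

test_that("Bland-Altman bias and limits of agreement", {
  expect_equal(unlist(bland_altman(make_paired(70:90, 70:90))[1:3]),
               c(bias = 0, loa_low = 0, loa_high = 0))
  ba5 <- bland_altman(rep(5, 10))       # constant difference, zero variance
  expect_equal(c(ba5$bias, ba5$loa_low, ba5$loa_high), c(5, 5, 5))
  set.seed(82)
  d <- rnorm(1e5, -1.4, 8)
  ba <- bland_altman(d)
  expect_lt(abs(ba$bias - (-1.4)), 3 * 8 / sqrt(1e5))
  # LoA half-width is exactly 1.96 * sample SD
  expect_equal(ba$loa_high - ba$bias, 1.96 * sd(d))
  expect_error(bland_altman(5), "at least 2")
})

test_that("Lin's CCC matches a direct-formula oracle and its bounds", {
  w <- c(61, 72, 83, 95, 101)
  c_ <- c(60, 70, 86, 92, 100)
  # independent direct transcription with population moments
  n <- 5
  mw <- sum(w) / n; mc <- sum(c_) / n
  sw2 <- sum((w - mw)^2) / n; sc2 <- sum((c_ - mc)^2) / n
  swc <- sum((w - mw) * (c_ - mc)) / n
  oracle <- 2 * swc / (sw2 + sc2 + (mw - mc)^2)
  expect_lt(abs(lin_ccc(list(w = w, c = c_)) - oracle), 1e-12)

  expect_equal(lin_ccc(make_paired(70:90, 70:90)), 1.0)
  expect_error(lin_ccc(make_paired(70:90, rep(80, 21))), "constant")

  # |CCC| <= |Pearson r|; equality when means and variances match
  set.seed(83)
  x <- rnorm(200, 80, 10); y <- x + rnorm(200, 5, 3)
  expect_lte(abs(lin_ccc(list(w = y, c = x))), abs(cor(y, x)))
  y2 <- (x - mean(x)) * -1 + mean(x)    # same mean and variance
  expect_equal(lin_ccc(list(w = y2, c = x)), cor(y2, x), tolerance = 1e-12)
})

test_that("CCC strength labels follow the printed cut points", {
  expect_equal(ccc_strength(0.872), "strong")
  expect_equal(ccc_strength(0.7), "moderate")
  expect_equal(ccc_strength(0.5), "moderate")
  expect_equal(ccc_strength(0.49), "weak")
})

test_that("the per-participant fit object carries a consistent panel", {
  set.seed(84)
  c0 <- 60 + rexp(500, 1 / 25)
  p <- make_paired(c0, c0 + rnorm(500, -1.4, 6))
  fit <- hr_agreement(p, id = "P07", device = "wrist")
  expect_s3_class(fit, "hr_agreement")
  expect_equal(fit$accuracy_pct, accuracy_within(p))
  expect_equal(fit$mae_bpm, mae(p))
  expect_equal(fit$bias_bpm, bland_altman(p)$bias)
  expect_equal(fit$ccc, lin_ccc(p))
  expect_true(fit$loa_low_bpm <= fit$bias_bpm && fit$bias_bpm <= fit$loa_high_bpm)
  expect_named(coef(fit), c("accuracy_pct", "mae_bpm", "mape_pct", "bias_bpm",
                            "loa_low_bpm", "loa_high_bpm", "ccc"))
  expect_output(print(fit), "Bland-Altman")
})

test_that("cohort summaries average participants unweighted", {
  set.seed(85)
  mk <- function(id, n, bias) {
    c0 <- 70 + rnorm(n, 0, 8)
    hr_agreement(make_paired(c0, c0 + rnorm(n, bias, 5)), id = id)
  }
  fits <- list(mk("A", 400, -3), mk("B", 100, 1), mk("C", 250, -1))
  co <- cohort_agreement(fits, boot = 200, boot_seed = 9)
  accs <- vapply(fits, function(f) f$accuracy_pct, 0)
  expect_equal(co$summary["accuracy_pct", "mean"], mean(accs))  # unweighted
  expect_equal(co$summary["ccc", "mean"], mean(vapply(fits, `[[`, 0, "ccc")))
  # pooled Bland-Altman pools samples, not participants
  all_d <- unlist(lapply(fits, `[[`, "differences"))
  expect_equal(co$pooled_bias_bpm, mean(all_d))
  expect_true(co$ccc_ci[1] <= co$mean_ccc && co$mean_ccc <= co$ccc_ci[2])

  # two identical participants -> zero SD everywhere
  twin <- list(mk("A", 300, -2), mk("A", 300, -2))
  set.seed(85)  # regenerate identically
  c0 <- 70 + rnorm(300, 0, 8)
  f1 <- hr_agreement(make_paired(c0, c0 + rnorm(300, -2, 5)), id = "A")
  co2 <- cohort_agreement(list(f1, f1), boot = 100, boot_seed = 2)
  expect_equal(unname(co2$summary[, "sd"]), rep(0, 4))
})
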
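## Agreement statistics between wearable and criterion heart rate.
##
## hr_agreement() is the per-participant estimator; it returns a classed
## object with coef/print/plot methods. cohort_agreement() aggregates a list
## of fits into cohort-level summaries (unweighted participant means, pooled
## Bland-Altman, bootstrap CI for the mean CCC).

## Usable pairs: criterion present, wearable present and non-zero, and the
## row not excluded as a criterion-device failure.
usable_pairs <- function(paired) {
  stopifnot(inherits(paired, "paired_series"))
  ok <- paired$missing_cause == "none" &
    !is.na(paired$wearable_bpm) & paired$wearable_bpm > 0 &
    !is.na(paired$criterion_bpm)
  list(w = paired$wearable_bpm[ok], c = paired$criterion_bpm[ok], n = sum(ok))
}

#' Within-tolerance (AAMI-style) accuracy
#'
#' Percentage of usable pairs whose wearable reading lies within `tolerance`
#' (default 10%, inclusive at the boundary) of the simultaneous criterion
#' value.
#'
#' @param paired a [resample_to_criterion()] result.
#' @param tolerance relative tolerance (0.10 = 10%).
#' @return Accuracy in percent.
#' @export
accuracy_within <- function(paired, tolerance = 0.10) {
  u <- usable_pairs(paired)
  if (u$n < 1) stop("no usable pairs")
  100 * mean(abs(u$w - u$c) / u$c <= tolerance)
}

#' Mean absolute error (BPM)
#'
#' @param paired a [resample_to_criterion()] result.
#' @return MAE in BPM.
#' @export
mae <- function(paired) {
  u <- usable_pairs(paired)
  if (u$n < 1) stop("no usable pairs")
  mean(abs(u$w - u$c))
}

#' Mean absolute percentage error
#'
#' `mean(|wearable - criterion| / criterion) * 100`. The absolute error is
#' used so over- and underestimation both count. Pairs with a criterion value
#' of 0 are excluded with a warning (division undefined); such values are
#' normally already filtered out as missing criterion data.
#'
#' @param paired a [resample_to_criterion()] result.
#' @return MAPE in percent.
#' @export
mape <- function(paired) {
  u <- usable_pairs(paired)
  if (u$n < 1) stop("no usable pairs")
  zero <- u$c == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with criterion 0 excluded from MAPE")
    u$w <- u$w[!zero]; u$c <- u$c[!zero]
  }
  100 * mean(abs(u$w - u$c) / u$c)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are `wearable - criterion`; bias is their mean and the limits
#' of agreement are `bias +/- 1.96 * sd` (sample SD, n-1 denominator).
#'
#' @param paired a [resample_to_criterion()] result, or a numeric vector of
#'   differences.
#' @return A list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(paired) {
  d <- if (inherits(paired, "paired_series")) {
    u <- usable_pairs(paired)
    u$w - u$c
  } else as.numeric(paired)
  if (length(d) < 2) stop("Bland-Altman needs at least 2 pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(w, c) / (var(w) + var(c) + (mean(w) - mean(c))^2)` with
#' population (n-denominator) moments, per Lin's definition. Penalizes both
#' poor correlation and location/scale shift.
#'
#' @param paired a [resample_to_criterion()] result, or a list/data.frame
#'   with elements `w` and `c`.
#' @return CCC in \[-1, 1\].
#' @export
lin_ccc <- function(paired) {
  u <- if (inherits(paired, "paired_series")) usable_pairs(paired)
       else list(w = as.numeric(paired$w), c = as.numeric(paired$c))
  n <- length(u$w)
  if (n < 3) stop("CCC needs at least 3 pairs")
  mw <- mean(u$w); mc <- mean(u$c)
  vw <- mean((u$w - mw)^2); vc <- mean((u$c - mc)^2)
  if (vw == 0 || vc == 0) stop("CCC undefined for a constant series")
  cv <- mean((u$w - mw) * (u$c - mc))
  2 * cv / (vw + vc + (mw - mc)^2)
}

#' Qualitative CCC strength label
#'
#' `weak` below 0.5, `moderate` in \[0.5, 0.7\], `strong` above 0.7.
#' @param ccc a concordance correlation coefficient.
#' @return `"weak"`, `"moderate"` or `"strong"`.
#' @export
ccc_strength <- function(ccc) {
  stopifnot(ccc >= -1, ccc <= 1)
  if (ccc < 0.5) "weak" else if (ccc <= 0.7) "moderate" else "strong"
}

#' Fit the full per-participant agreement panel
#'
#' The one-stop estimator: computes within-10% accuracy, MAE, MAPE,
#' Bland-Altman bias and limits of agreement, and Lin's CCC from one
#' participant-device paired series. Returns a classed object; use `coef()`
#' for the metric vector, `print()` for a summary and `plot()` for the
#' Bland-Altman plot.
#'
#' @param paired a [resample_to_criterion()] result.
#' @param id participant id (defaults to the series attribute).
#' @param device device label.
#' @param tolerance accuracy tolerance (relative).
#' @return An object of class `hr_agreement`.
#' @export
hr_agreement <- function(paired, id = attr(paired, "participant"),
                         device = "wearable", tolerance = 0.10) {
  u <- usable_pairs(paired)
  if (u$n < 3) stop("hr_agreement needs at least 3 usable pairs")
  ba <- bland_altman(u$w - u$c)
  ccc <- lin_ccc(list(w = u$w, c = u$c))
  structure(list(
    id = id, device = device, n_pairs = u$n,
    accuracy_pct = 100 * mean(abs(u$w - u$c) / u$c <= tolerance),
    mae_bpm = mean(abs(u$w - u$c)),
    mape_pct = 100 * mean(abs(u$w - u$c) / u$c),
    bias_bpm = ba$bias, loa_low_bpm = ba$loa_low, loa_high_bpm = ba$loa_high,
    sd_diff_bpm = ba$sd_diff,
    ccc = ccc, ccc_strength = ccc_strength(ccc),
    tolerance = tolerance,
    differences = u$w - u$c, means = (u$w + u$c) / 2),
    class = "hr_agreement")
}

#' @export
coef.hr_agreement <- function(object, ...) {
  c(accuracy_pct = object$accuracy_pct, mae_bpm = object$mae_bpm,
    mape_pct = object$mape_pct, bias_bpm = object$bias_bpm,
    loa_low_bpm = object$loa_low_bpm, loa_high_bpm = object$loa_high_bpm,
    ccc = object$ccc)
}

#' @export
print.hr_agreement <- function(x, ...) {
  cat(sprintf("Heart-rate agreement: %s%s (%d pairs)\n",
              ifelse(is.null(x$id), "<participant>", x$id),
              ifelse(is.null(x$device), "", paste0(" / ", x$device)), x$n_pairs))
  cat(sprintf("  accuracy within %.0f%%: %.1f%%\n", 100 * x$tolerance, x$accuracy_pct))
  cat(sprintf("  MAE %.2f BPM, MAPE %.2f%%\n", x$mae_bpm, x$mape_pct))
  cat(sprintf("  Bland-Altman bias %.2f BPM, 95%% LoA [%.2f, %.2f]\n",
              x$bias_bpm, x$loa_low_bpm, x$loa_high_bpm))
  cat(sprintf("  Lin CCC %.3f (%s)\n", x$ccc, x$ccc_strength))
  invisible(x)
}

#' @export
plot.hr_agreement <- function(x, ...) {
  graphics::plot(x$means, x$differences, pch = ".", col = "grey40",
                 xlab = "Mean of wearable and criterion (BPM)",
                 ylab = "Wearable - criterion (BPM)",
                 main = sprintf("Bland-Altman: %s", ifelse(is.null(x$id), "", x$id)),
                 ...)
  graphics::abline(h = x$bias_bpm, col = "firebrick", lwd = 2)
  graphics::abline(h = c(x$loa_low_bpm, x$loa_high_bpm), col = "firebrick",
                   lty = 2)
  invisible(x)
}

#' Cohort-level agreement summary
#'
#' Per-participant metrics are averaged unweighted across participants
#' (individual values averaged, mean and SD reported). The Bland-Altman bias
#' and limits of agreement are additionally pooled over all samples, which is
#' the scale on which sample-level LoA of roughly +/-18 BPM arise; the mean
#' CCC gets a 95% percentile bootstrap CI resampling participants (honest for
#' clustered data), with `ci_method = "pooled"` available for comparability
#' with pooled-sample asymptotics.
#'
#' @param fits list of [hr_agreement()] objects (>= 2 participants).
#' @param boot number of bootstrap resamples for the CCC CI.
#' @param boot_seed RNG seed of the bootstrap.
#' @param ci_method `"participant_bootstrap"` (default) or `"pooled"` (Fisher
#'   z-type asymptotic CI on the pooled CCC).
#' @return An object of class `cohort_agreement`.
#' @export
cohort_agreement <- function(fits, boot = 2000, boot_seed = 1,
                             ci_method = c("participant_bootstrap", "pooled")) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "hr_agreement")))
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(id = ifelse(is.null(f$id), NA, f$id), device = f$device,
               n_pairs = f$n_pairs, accuracy_pct = f$accuracy_pct,
               mae_bpm = f$mae_bpm, mape_pct = f$mape_pct,
               bias_bpm = f$bias_bpm, loa_low_bpm = f$loa_low_bpm,
               loa_high_bpm = f$loa_high_bpm, ccc = f$ccc)))
  msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
  summary_tab <- rbind(accuracy_pct = msd(tab$accuracy_pct),
                       mae_bpm = msd(tab$mae_bpm),
                       mape_pct = msd(tab$mape_pct),
                       ccc = msd(tab$ccc))
  pooled_d <- unlist(lapply(fits, `[[`, "differences"))
  pooled_ba <- bland_altman(pooled_d)
  mean_ccc <- mean(tab$ccc)
  ci <- if (ci_method == "participant_bootstrap") {
    with_seed(boot_seed, {
      bs <- replicate(boot, mean(tab$ccc[sample.int(nrow(tab), replace = TRUE)]))
      stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    })
  } else {
    ## pooled-sample asymptotic CI via Fisher's z on the pooled CCC
    wc <- list(w = unlist(lapply(fits, function(f) f$means + f$differences / 2)),
               c = unlist(lapply(fits, function(f) f$means - f$differences / 2)))
    cc <- lin_ccc(wc)
    n <- length(wc$w)
    z <- atanh(cc); se <- 1 / sqrt(n - 3)
    tanh(z + c(-1.96, 1.96) * se)
  }
  structure(list(per_participant = tab, summary = summary_tab,
                 pooled_bias_bpm = pooled_ba$bias,
                 pooled_loa_low_bpm = pooled_ba$loa_low,
                 pooled_loa_high_bpm = pooled_ba$loa_high,
                 pooled_sd_diff_bpm = pooled_ba$sd_diff,
                 mean_ccc = mean_ccc, ccc_ci = ci, ci_method = ci_method,
                 n_participants = nrow(tab),
                 pooled_differences = pooled_d,
                 pooled_means = unlist(lapply(fits, `[[`, "means"))),
            class = "cohort_agreement")
}

#' @export
print.cohort_agreement <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Cohort agreement over %d participants\n", x$n_participants))
  cat(sprintf("  accuracy %.1f%% (SD %.1f)   MAE %.2f (SD %.2f) BPM   MAPE %.2f%% (SD %.2f)\n",
              s["accuracy_pct", "mean"], s["accuracy_pct", "sd"],
              s["mae_bpm", "mean"], s["mae_bpm", "sd"],
              s["mape_pct", "mean"], s["mape_pct", "sd"]))
  cat(sprintf("  pooled Bland-Altman bias %.2f BPM, 95%% LoA [%.2f, %.2f]\n",
              x$pooled_bias_bpm, x$pooled_loa_low_bpm, x$pooled_loa_high_bpm))
  cat(sprintf("  mean CCC %.3f (95%% CI %.3f-%.3f, %s) -> %s\n",
              x$mean_ccc, x$ccc_ci[1], x$ccc_ci[2], x$ci_method,
              ccc_strength(x$mean_ccc)))
  invisible(x)
}

#' @export
summary.cohort_agreement <- function(object, ...) {
  object$per_participant
}

#' @export
plot.cohort_agreement <- function(x, ...) {
  graphics::plot(x$pooled_means, x$pooled_differences, pch = ".", col = "grey40",
                 xlab = "Mean of wearable and criterion (BPM)",
                 ylab = "Wearable - criterion (BPM)",
                 main = "Pooled Bland-Altman", ...)
  graphics::abline(h = x$pooled_bias_bpm, col = "firebrick", lwd = 2)
  graphics::abline(h = c(x$pooled_loa_low_bpm, x$pooled_loa_high_bpm),
                   col = "firebrick", lty = 2)
  invisible(x)
}
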
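## Subgroup stratification and the normality-gated significance tests.
##
## Between-participant schemes (sex, age, BMI, wrist, skin type, diagnosis)
## compare one overall accuracy value per participant across groups;
## within-participant schemes (HR above/below own median, sleep/wake, first
## vs second 12 h) compare per-stratum accuracies of the same participants.
## Shapiro-Wilk at alpha = 0.05 per group gates parametric tests (t / paired
## t / ANOVA) against their nonparametric equivalents (Mann-Whitney /
## Wilcoxon signed-rank / Kruskal-Wallis). Test selection is structurally
## enforced: a within-participant scheme can never dispatch to an
## independent-samples test.

#' Label paired rows as wake, sleep or excluded
#'
#' Rows within half the guard window of each diary transition (sleep onset
#' and wake) are excluded — the default 60-minute guard, read as a symmetric
#' +/-30 min around each reported time, removes the ill-defined transition
#' period from the sleep-vs-wake contrast. Remaining rows are `sleep` inside
#' `[onset, wake)` and `wake` otherwise.
#'
#' @param paired a [resample_to_criterion()] result.
#' @param diary a [read_diary()] result (NULL skips the scheme).
#' @param guard_min total guard window around each transition, minutes.
#' @return Character vector of labels `wake`/`sleep`/`excluded`, or NULL with
#'   a message when no diary is available.
#' @export
split_sleep_wake <- function(paired, diary, guard_min = 60) {
  if (is.null(diary) || !nrow(diary)) {
    message("no diary: sleep/wake scheme skipped for this participant")
    return(NULL)
  }
  half <- guard_min * 60 / 2
  lab <- rep("wake", nrow(paired))
  for (i in seq_len(nrow(diary))) {
    lab[paired$t >= diary$sleep_onset_s[i] & paired$t < diary$wake_s[i]] <- "sleep"
  }
  for (tr in c(diary$sleep_onset_s, diary$wake_s)) {
    lab[paired$t >= tr - half & paired$t < tr + half] <- "excluded"
  }
  lab
}

#' Label paired rows as below/above the participant's own median heart rate
#'
#' The median (not the mean) is the threshold because the mean is pulled by
#' outliers; ties go to `low` (the comparison is `<=`).
#'
#' @param paired a [resample_to_criterion()] result.
#' @return Character vector of labels `low`/`high` (`NA` where the criterion
#'   is missing).
#' @export
split_hr_median <- function(paired) {
  if (sum(!is.na(paired$criterion_bpm)) < 2) stop("need at least 2 criterion values")
  med <- stats::median(paired$criterion_bpm, na.rm = TRUE)
  ifelse(is.na(paired$criterion_bpm), NA_character_,
         ifelse(paired$criterion_bpm <= med, "low", "high"))
}

#' Label paired rows by measuring period (first vs second half)
#'
#' @param paired a [resample_to_criterion()] result.
#' @param period_h half-period in hours (default 12: first vs second 12 h).
#' @return Character labels `first`/`second`, or NULL with a message when the
#'   recording is shorter than two periods.
#' @export
split_period <- function(paired, period_h = 12) {
  span <- diff(range(paired$t))
  if (span < 2 * period_h * 3600) {
    message(sprintf("recording spans %.1f h < %.0f h: period scheme skipped",
                    span / 3600, 2 * period_h))
    return(NULL)
  }
  ifelse(paired$t - min(paired$t) < period_h * 3600, "first", "second")
}

## Shapiro-Wilk normality gate; constant or tiny samples count as non-normal
## (the parametric test's assumptions cannot be verified).
normal_ok <- function(x, alpha = 0.05) {
  if (length(x) < 3 || length(unique(x)) == 1) return(list(ok = FALSE, p = NA_real_))
  p <- stats::shapiro.test(x)$p.value
  list(ok = p >= alpha, p = p)
}

#' Normality-gated subgroup significance test
#'
#' For between-participant schemes each participant contributes one value to
#' exactly one group: two groups get an independent t test (Welch) or
#' Mann-Whitney; more get one-way ANOVA or Kruskal-Wallis. For
#' within-participant schemes each participant contributes one value per
#' group (two groups only): paired t test or Wilcoxon signed-rank, gated on
#' the normality of the paired differences. All tests are two-sided;
#' normality is judged by Shapiro-Wilk at alpha = 0.05 per group.
#'
#' @param df data.frame with columns `participant`, `group`, `value`.
#' @param kind `"between_participant"` or `"within_participant"`.
#' @param scheme optional scheme name carried into the result.
#' @return A list of class `subgroup_result`: `scheme`, `kind`, `test_used`,
#'   `p_value`, `normality_p` (per group), `groups` (per-group n/mean/sd).
#' @export
subgroup_test <- function(df, kind = c("between_participant", "within_participant"),
                          scheme = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(c("participant", "group", "value") %in% names(df)))
  df <- df[!is.na(df$value) & !is.na(df$group), , drop = FALSE]
  groups <- sort(unique(as.character(df$group)))
  if (length(groups) < 2) stop("subgroup test needs at least 2 groups",
                               if (!is.null(scheme)) paste0(" (scheme ", scheme, ")"))
  split_vals <- split(df$value, as.character(df$group))
  ns <- vapply(split_vals, length, 0L)
  if (any(ns < 3))
    stop(sprintf("group '%s' has n = %d < 3%s", names(ns)[which.min(ns)], min(ns),
                 if (!is.null(scheme)) paste0(" (scheme ", scheme, ")") else ""))

  gstats <- data.frame(group = groups,
                       n = ns[groups],
                       mean = vapply(split_vals[groups], mean, 0),
                       sd = vapply(split_vals[groups], stats::sd, 0),
                       row.names = NULL)

  if (kind == "within_participant") {
    if (length(groups) != 2)
      stop("within-participant schemes support exactly 2 groups")
    wide <- stats::reshape(df[c("participant", "group", "value")],
                           idvar = "participant", timevar = "group",
                           direction = "wide")
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    if (nrow(wide) < 3) stop("fewer than 3 participants with both strata")
    d <- wide[[paste0("value.", groups[1])]] - wide[[paste0("value.", groups[2])]]
    norm <- normal_ok(d)
    if (all(d == 0)) {
      test_used <- "degenerate"; p <- 1
    } else if (norm$ok) {
      test_used <- "paired-t"
      p <- stats::t.test(d)$p.value
    } else {
      test_used <- "Wilcoxon"
      p <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
    }
    normality_p <- c(differences = norm$p)
  } else {
    norms <- lapply(split_vals[groups], normal_ok)
    normality_p <- vapply(norms, `[[`, 0, "p")
    names(normality_p) <- groups
    all_normal <- all(vapply(norms, `[[`, TRUE, "ok"))
    if (all(vapply(split_vals, function(v) length(unique(v)) == 1, TRUE)) &&
        length(unique(df$value)) == 1) {
      test_used <- "degenerate"; p <- 1
    } else if (length(groups) == 2) {
      if (all_normal) {
        test_used <- "t"
        p <- stats::t.test(split_vals[[groups[1]]], split_vals[[groups[2]]])$p.value
      } else {
        test_used <- "Mann-Whitney"
        p <- stats::wilcox.test(split_vals[[groups[1]]], split_vals[[groups[2]]],
                                exact = FALSE, correct = TRUE)$p.value
      }
    } else {
      if (all_normal) {
        test_used <- "ANOVA"
        p <- summary(stats::aov(value ~ factor(group), data = df))[[1]][["Pr(>F)"]][1]
      } else {
        test_used <- "Kruskal-Wallis"
        p <- stats::kruskal.test(df$value, factor(df$group))$p.value
      }
    }
  }
  structure(list(scheme = scheme, kind = kind, test_used = test_used,
                 p_value = p, normality_p = normality_p, groups = gstats),
            class = "subgroup_result")
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat(sprintf("Subgroup '%s' (%s): %s test, p = %.4g\n",
              ifelse(is.null(x$scheme), "?", x$scheme), x$kind, x$test_used,
              x$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Mean accuracy per movement quantile across participants
#'
#' One row per quantile bin: the unweighted mean (SD) across participants of
#' each participant's within-bin accuracy. Participants flagged with a
#' sample-rate anomaly are excluded (their nominal stream is too sparse for
#' the accelerometry pairing). With one participant the SD is `NA`.
#'
#' @param bin_accuracy data.frame with columns `participant`, `quantile`,
#'   `accuracy_pct` (one row per participant per bin).
#' @param exclude participant ids to drop (e.g. sample-rate-flagged).
#' @param k number of bins.
#' @return data.frame with `quantile`, `n`, `mean_accuracy_pct`, `sd_accuracy_pct`.
#' @export
quantile_accuracy_table <- function(bin_accuracy, exclude = character(0), k = 4) {
  b <- bin_accuracy[!bin_accuracy$participant %in% exclude, , drop = FALSE]
  out <- lapply(seq_len(k), function(q) {
    v <- b$accuracy_pct[b$quantile == q]
    data.frame(quantile = q, n = length(v),
               mean_accuracy_pct = if (length(v)) mean(v) else NA_real_,
               sd_accuracy_pct = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  do.call(rbind, out)
}

#' Age-group x movement interaction regression on bin-level accuracy
#'
#' Ordinary least squares with one observation per participant x quantile
#' bin: outcome is the participant's accuracy in the bin, predictors are age
#' group (<=12 vs >12 years), the participant's mean movement intensity in
#' that bin (g), and their interaction. The bin-level unit avoids the
#' pseudo-replication a per-sample regression would incur.
#'
#' @param df data.frame with columns `participant`, `age_group` (factor with
#'   2 levels), `movement_g`, `accuracy_pct`.
#' @return A list of class `accel_regression`: `coefficients` (estimate, se,
#'   t, p per term), `interaction_p`, and the underlying `lm` fit.
#' @export
accel_accuracy_regression <- function(df) {
  stopifnot(all(c("age_group", "movement_g", "accuracy_pct") %in% names(df)))
  df$age_group <- factor(df$age_group)
  if (nlevels(df$age_group) != 2) stop("age_group must have exactly 2 levels")
  fit <- stats::lm(accuracy_pct ~ age_group * movement_g, data = df)
  if (fit$rank < 4) stop("rank-deficient design: predictors are collinear")
  ct <- summary(fit)$coefficients
  inter <- grep(":", rownames(ct), value = TRUE)
  structure(list(coefficients = ct, interaction_p = ct[inter, "Pr(>|t|)"],
                 fit = fit),
            class = "accel_regression")
}

#' @export
print.accel_regression <- function(x, ...) {
  cat("Accuracy ~ age_group * movement (OLS, participant x quantile bins)\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Interaction p = %.4g\n", x$interaction_p))
  invisible(x)
}

#' Comfort-score summary and device comparisons
#'
#' Composite comfort per respondent and device is the mean item score;
#' cohort summaries are medians with IQR. Each wearable is compared with the
#' criterion device by a two-sided Wilcoxon signed-rank test on the paired
#' composites (Likert data are ordinal, so only nonparametric comparisons
#' are made). Respondents lacking the criterion rating are dropped with a
#' message.
#'
#' @param responses data.frame with columns `participant`, `device`, item
#'   columns `q1`, `q2`, ... and optionally `wear_time_h`.
#' @return A list of class `comfort_summary`: `composite` (per participant x
#'   device), `device_summary` (median, IQR), `item_medians`, `tests`.
#' @export
comfort_summary <- function(responses) {
  items <- grep("^q[0-9]+$", names(responses), value = TRUE)
  if (!length(items)) stop("no item columns (q1, q2, ...)")
  comp <- data.frame(participant = responses$participant,
                     device = responses$device,
                     composite = rowMeans(responses[items]))
  has_crit <- unique(comp$participant[comp$device == "criterion"])
  dropped <- setdiff(unique(comp$participant), has_crit)
  if (length(dropped)) {
    message(length(dropped), " respondent(s) without a criterion rating dropped")
    comp <- comp[comp$participant %in% has_crit, , drop = FALSE]
  }
  devs <- unique(comp$device)
  device_summary <- do.call(rbind, lapply(devs, function(d) {
    v <- comp$composite[comp$device == d]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(device = d, n = length(v), median = q[2], iqr_low = q[1],
               iqr_high = q[3])
  }))
  item_medians <- do.call(rbind, lapply(devs, function(d) {
    r <- responses[responses$device == d, items, drop = FALSE]
    data.frame(device = d, item = items,
               median = vapply(items, function(it) stats::median(r[[it]]), 0))
  }))
  tests <- list()
  for (d in setdiff(devs, "criterion")) {
    both <- intersect(comp$participant[comp$device == d], has_crit)
    dw <- comp$composite[comp$device == d][match(both, comp$participant[comp$device == d])]
    dc <- comp$composite[comp$device == "criterion"][match(both, comp$participant[comp$device == "criterion"])]
    diffs <- dw - dc
    tests[[d]] <- list(
      n = length(both), median_difference = stats::median(diffs),
      p_value = if (all(diffs == 0)) 1
                else stats::wilcox.test(diffs, exact = FALSE, correct = TRUE)$p.value)
  }
  structure(list(composite = comp, device_summary = device_summary,
                 item_medians = item_medians, tests = tests),
            class = "comfort_summary")
}

#' @export
print.comfort_summary <- function(x, ...) {
  cat("Comfort scores (composite = mean item score per respondent)\n")
  print(x$device_summary, row.names = FALSE)
  for (d in names(x$tests)) {
    cat(sprintf("  %s vs criterion: median diff %+.2f, Wilcoxon p = %.4g (n = %d)\n",
                d, x$tests[[d]]$median_difference, x$tests[[d]]$p_value,
                x$tests[[d]]$n))
  }
  invisible(x)
}
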
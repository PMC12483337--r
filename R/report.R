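## End-to-end pipeline: per-participant sync + validation, then cohort
## assembly into machine-readable tables (participant characteristics,
## agreement, quantile-accuracy, subgroup, comfort) with a deterministic
## JSON report.

#' Synchronize and validate one participant
#'
#' Runs the full per-participant chain: criterion HR (16-beat moving average
#' when the criterion arrives as R-R intervals), cross-correlation clock
#' offset, interpolation onto criterion timestamps, missingness
#' classification, movement quantiles and the agreement fit.
#'
#' @param p a [read_participant()] result (or the in-memory equivalent).
#' @param config list of knobs: `window_beats` (16), `max_lag_s` (60),
#'   `max_bridge_gap_s` (60), `tolerance` (0.10), `quantile_k` (4),
#'   `movement_tol_s` (2).
#' @return A list of class `participant_result`: `id`, `meta`, `sync`,
#'   `paired`, `missingness`, `movement`, `quantile_profile`, `labels`,
#'   `fit`.
#' @export
validate_participant <- function(p, config = list()) {
  cfg <- utils::modifyList(list(window_beats = 16, max_lag_s = 60,
                                max_bridge_gap_s = 60, tolerance = 0.10,
                                quantile_k = 4, movement_tol_s = 2), config)
  criterion <- if (!is.null(p$rr)) hr_from_rr(p$rr, cfg$window_beats)
               else p$criterion_hr
  sync <- estimate_offset(criterion, p$wearable, max_lag_s = cfg$max_lag_s)
  paired <- resample_to_criterion(p$wearable, criterion, sync$offset_s,
                                  max_bridge_gap_s = cfg$max_bridge_gap_s)
  miss <- classify_missing(paired, p$wearable)
  movement <- accel_magnitude(p$accel)
  qp <- quantile_profile(movement, k = cfg$quantile_k)
  labels <- if (miss$samplerate_anomaly) rep(NA_integer_, nrow(paired))
            else assign_quantiles(paired, movement, qp, tol_s = cfg$movement_tol_s)
  fit <- hr_agreement(paired, id = p$meta$id, tolerance = cfg$tolerance)
  structure(list(id = p$meta$id, meta = p$meta, sync = sync, paired = paired,
                 missingness = miss, movement = movement,
                 quantile_profile = qp, labels = labels, fit = fit,
                 diary = p$diary, config = cfg),
            class = "participant_result")
}

## accuracy of a paired subset; NA when too few usable pairs
subset_accuracy <- function(paired, rows, tolerance = 0.10, min_pairs = 10) {
  sub <- paired[rows, , drop = FALSE]
  class(sub) <- class(paired)
  u <- usable_pairs(sub)
  if (u$n < min_pairs) return(NA_real_)
  100 * mean(abs(u$w - u$c) / u$c <= tolerance)
}

## per-participant per-quantile accuracy and mean movement intensity
bin_accuracy_frame <- function(res) {
  k <- res$config$quantile_k
  g <- nearest_value(res$movement$t, res$movement$intensity_g, res$paired$t,
                     tol = res$config$movement_tol_s)
  out <- lapply(seq_len(k), function(q) {
    rows <- !is.na(res$labels) & res$labels == q
    data.frame(participant = res$id, quantile = q,
               accuracy_pct = subset_accuracy(res$paired, rows,
                                              res$config$tolerance),
               movement_g = if (any(rows)) mean(g[rows], na.rm = TRUE) else NA_real_)
  })
  do.call(rbind, out)
}

fitzpatrick_group <- function(fp, grouping = c("methods", "table")) {
  grouping <- match.arg(grouping)
  if (is.null(fp) || is.na(fp)) return(NA_character_)
  if (grouping == "methods") {
    ## {I,II} / {III} / {IV,V,VI}
    switch(fp, I = "I-II", II = "I-II", III = "III", "IV-VI")
  } else {
    ## {I,II} / {III,IV} / {V,VI}
    switch(fp, I = "I-II", II = "I-II", III = "III-IV", IV = "III-IV", "V-VI")
  }
}

between_schemes <- function(metas, fitz_grouping = "methods") {
  lab <- function(f) vapply(metas, f, "")
  list(
    sex = lab(function(m) m$sex),
    age = lab(function(m) if (m$age_years <= 12) "<=12y" else ">12y"),
    bmi = lab(function(m) if (m$bmi_kg_m2 <= 19) "<=19" else ">19"),
    diagnosis = lab(function(m) m$indication),
    wrist = lab(function(m) if (is.null(m$wrist_circumference_cm)) NA_character_
                else if (m$wrist_circumference_cm <= 15.5) "<=15.5cm" else ">15.5cm"),
    fitzpatrick = lab(function(m)
      fitzpatrick_group(m$fitzpatrick, fitz_grouping))
  )
}

within_schemes <- function(res, guard_min = 60) {
  out <- list()
  hr_lab <- split_hr_median(res$paired)
  out$heart_rate <- list(labels = hr_lab, levels = c("low", "high"))
  sw <- suppressMessages(split_sleep_wake(res$paired, res$diary, guard_min))
  if (!is.null(sw)) out$time_of_day <- list(labels = ifelse(sw == "excluded", NA, sw),
                                            levels = c("wake", "sleep"))
  pr <- suppressMessages(split_period(res$paired))
  if (!is.null(pr)) out$period <- list(labels = pr, levels = c("first", "second"))
  out
}

#' Build the full cohort validation report
#'
#' Reads every participant directory under `cohort_dir`, runs
#' [validate_participant()] on each, and assembles: participant
#' characteristics, the per-participant and cohort agreement tables, the
#' missingness summary (with sample-rate anomaly flags), the
#' movement-quantile accuracy table (flagged participants excluded), the
#' subgroup analysis (between- and within-participant schemes with
#' normality-gated tests), the age-group x movement interaction regression
#' and the comfort-score summary. When `out_dir` is given, writes
#' `report.json`, `participants.csv` and `report.md`; reruns on the same
#' cohort are byte-identical.
#'
#' @param cohort_dir directory of participant directories (as written by
#'   [gen_cohort()]).
#' @param config passed to [validate_participant()]; additional entries:
#'   `guard_min` (60), `fitz_grouping` (`"methods"` or `"table"`),
#'   `boot` (2000), `boot_seed` (1).
#' @param out_dir optional output directory.
#' @return An object of class `cohort_report`.
#' @export
build_report <- function(cohort_dir, config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(guard_min = 60, fitz_grouping = "methods",
                                boot = 2000, boot_seed = 1), config)
  pdirs <- sort(list.dirs(cohort_dir, recursive = FALSE))
  pdirs <- pdirs[file.exists(file.path(pdirs, "meta.yaml"))]
  if (!length(pdirs)) stop("no participant directories found in ", cohort_dir)
  results <- lapply(pdirs, function(d) validate_participant(read_participant(d), cfg))
  names(results) <- vapply(results, `[[`, "", "id")
  report_from_results(results, cohort_dir, cfg, out_dir)
}

report_from_results <- function(results, cohort_dir, cfg, out_dir = NULL) {
  metas <- lapply(results, `[[`, "meta")
  ids <- names(results)

  characteristics <- list(
    n = length(results),
    age_mean = mean(vapply(metas, `[[`, 0, "age_years")),
    age_sd = stats::sd(vapply(metas, `[[`, 0, "age_years")),
    female_n = sum(vapply(metas, `[[`, "", "sex") == "female"),
    bmi_mean = mean(vapply(metas, `[[`, 0, "bmi_kg_m2")),
    indication = as.list(table(vapply(metas, `[[`, "", "indication"))))

  cohort <- cohort_agreement(lapply(results, `[[`, "fit"),
                             boot = cfg$boot, boot_seed = cfg$boot_seed)

  miss_tab <- do.call(rbind, lapply(results, function(r)
    data.frame(participant = r$id,
               pct_underdetected = r$missingness$pct_underdetected,
               pct_erroneous = r$missingness$pct_erroneous,
               samplerate_anomaly = r$missingness$samplerate_anomaly,
               offset_s = r$sync$offset_s,
               peak_correlation = r$sync$peak_correlation)))
  flagged <- miss_tab$participant[miss_tab$samplerate_anomaly]

  bins <- do.call(rbind, lapply(results, bin_accuracy_frame))
  qtab <- quantile_accuracy_table(bins, exclude = flagged,
                                  k = results[[1]]$config$quantile_k)

  ## subgroup analysis ------------------------------------------------------
  overall_acc <- vapply(results, function(r) r$fit$accuracy_pct, 0)
  subgroups <- list()
  for (nm in names(bs <- between_schemes(metas, cfg$fitz_grouping))) {
    grp <- bs[[nm]]
    df <- data.frame(participant = ids, group = grp, value = overall_acc)
    subgroups[[nm]] <- tryCatch(
      subgroup_test(df, "between_participant", scheme = nm),
      error = function(e) list(scheme = nm, skipped = conditionMessage(e)))
  }
  for (nm in c("heart_rate", "time_of_day", "period")) {
    rows <- list()
    for (r in results) {
      ws <- within_schemes(r, cfg$guard_min)
      if (is.null(ws[[nm]])) next
      lab <- ws[[nm]]$labels
      for (lev in ws[[nm]]$levels) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = r$id, group = lev,
          value = subset_accuracy(r$paired, !is.na(lab) & lab == lev,
                                  r$config$tolerance))
      }
    }
    if (!length(rows)) next
    df <- do.call(rbind, rows)
    subgroups[[nm]] <- tryCatch(
      subgroup_test(df, "within_participant", scheme = nm),
      error = function(e) list(scheme = nm, skipped = conditionMessage(e)))
  }

  ## age x movement interaction regression ----------------------------------
  age_grp <- vapply(metas, function(m) if (m$age_years <= 12) "<=12y" else ">12y", "")
  reg_df <- merge(bins, data.frame(participant = ids, age_group = age_grp),
                  by = "participant")
  reg_df <- reg_df[!reg_df$participant %in% flagged &
                     stats::complete.cases(reg_df), , drop = FALSE]
  regression <- if (length(unique(reg_df$age_group)) == 2 && nrow(reg_df) >= 8)
    tryCatch(accel_accuracy_regression(reg_df),
             error = function(e) list(skipped = conditionMessage(e)))
  else list(skipped = "insufficient data for the interaction regression")

  ## comfort ----------------------------------------------------------------
  qrows <- list()
  for (id in ids) {
    qp <- file.path(cohort_dir, id, "questionnaire.csv")
    if (file.exists(qp)) {
      q <- read_questionnaire(qp)
      q$participant <- id
      qrows[[id]] <- as.data.frame(q)
    }
  }
  comfort <- if (length(qrows) >= 3)
    suppressMessages(comfort_summary(do.call(rbind, qrows)))
  else list(skipped = "fewer than 3 questionnaires")

  rep <- structure(list(characteristics = characteristics, cohort = cohort,
                        missingness = miss_tab, flagged = as.character(flagged),
                        quantile_table = qtab, bin_accuracy = bins,
                        subgroups = subgroups, regression = regression,
                        comfort = comfort, results = results, config = cfg),
                   class = "cohort_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

subgroup_json <- function(sg) {
  if (!is.null(sg$skipped)) return(list(scheme = sg$scheme, skipped = sg$skipped))
  list(scheme = sg$scheme, kind = sg$kind, test_used = sg$test_used,
       p_value = sg$p_value, groups = sg$groups)
}

#' Write a cohort report to disk
#'
#' Emits `report.json` (every table, machine-readable), `participants.csv`
#' (per-participant agreement metrics) and a human-readable `report.md`.
#' Output is deterministic: rerunning on the same cohort reproduces the
#' files byte for byte.
#'
#' @param rep a [build_report()] result.
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(rep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per <- rep$cohort$per_participant
  utils::write.csv(per, file.path(out_dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  j <- list(
    characteristics = rep$characteristics,
    agreement = list(
      summary = as.data.frame(cbind(metric = rownames(rep$cohort$summary),
                                    as.data.frame(rep$cohort$summary))),
      pooled_bias_bpm = rep$cohort$pooled_bias_bpm,
      pooled_loa_bpm = c(rep$cohort$pooled_loa_low_bpm, rep$cohort$pooled_loa_high_bpm),
      mean_ccc = rep$cohort$mean_ccc,
      ccc_ci = as.numeric(rep$cohort$ccc_ci),
      ccc_strength = ccc_strength(rep$cohort$mean_ccc)),
    missingness = rep$missingness,
    flagged_samplerate = rep$flagged,
    quantile_accuracy = rep$quantile_table,
    subgroups = lapply(rep$subgroups, subgroup_json),
    regression = if (!is.null(rep$regression$skipped))
      list(skipped = rep$regression$skipped)
    else list(coefficients = as.data.frame(cbind(term = rownames(rep$regression$coefficients),
                                                 as.data.frame(rep$regression$coefficients))),
              interaction_p = rep$regression$interaction_p),
    comfort = if (!is.null(rep$comfort$skipped)) list(skipped = rep$comfort$skipped)
    else list(device_summary = rep$comfort$device_summary,
              tests = rep$comfort$tests))
  json <- jsonlite::toJSON(j, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  writeLines(json, file.path(out_dir, "report.json"))
  md <- c("# Cohort validation report", "",
          sprintf("Participants: %d (mean age %.1f y, %d female)",
                  rep$characteristics$n, rep$characteristics$age_mean,
                  rep$characteristics$female_n), "",
          sprintf("Mean accuracy %.1f%% (SD %.1f); MAE %.2f BPM; MAPE %.2f%%",
                  rep$cohort$summary["accuracy_pct", "mean"],
                  rep$cohort$summary["accuracy_pct", "sd"],
                  rep$cohort$summary["mae_bpm", "mean"],
                  rep$cohort$summary["mape_pct", "mean"]),
          sprintf("Pooled Bland-Altman bias %.2f BPM, 95%% LoA [%.2f, %.2f]",
                  rep$cohort$pooled_bias_bpm, rep$cohort$pooled_loa_low_bpm,
                  rep$cohort$pooled_loa_high_bpm),
          sprintf("Mean CCC %.3f (%s)", rep$cohort$mean_ccc,
                  ccc_strength(rep$cohort$mean_ccc)), "",
          "## Accuracy by movement quantile", "",
          utils::capture.output(print(rep$quantile_table, row.names = FALSE)))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d participants from a %s cohort\n",
              x$characteristics$n, "validated"))
  print(x$cohort)
  cat("Accuracy by movement quantile (flagged participants excluded):\n")
  print(x$quantile_table, row.names = FALSE)
  for (sg in x$subgroups) {
    if (!is.null(sg$skipped)) {
      cat(sprintf("  subgroup '%s': skipped (%s)\n", sg$scheme, sg$skipped))
    } else {
      cat(sprintf("  subgroup '%s': %s, p = %.4g\n", sg$scheme, sg$test_used,
                  sg$p_value))
    }
  }
  invisible(x)
}
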
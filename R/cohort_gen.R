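## Cohort-level simulation: samples participant metadata, a truth profile and
## an error model per participant, writes the on-disk layout used by
## read_participant(), and keeps a ledger of every injected truth so
## downstream recovery can be checked.

#' Scenario configuration for a synthetic cohort
#'
#' Defaults emulate the study conditions of a pediatric 24-hour validation
#' cohort: ages about 13 (SD 3.6) years truncated to \[6, 18\], ~45% female,
#' BMI about 19.9 (SD 3.7), wrist circumference 15.4 (SD 1.7) cm, Fitzpatrick
#' and indication frequencies matching a mixed congenital-heart-disease /
#' arrhythmia / symptoms clinic population; wearable bias -1.4 BPM, ~2.5%
#' dropout at rest emitted as zeros, integer clock offsets uniform on
#' \[-60, 60\] s, and motion-coupled noise.
#'
#' @param duration_s recording length per participant.
#' @param criterion_source `"rr"` writes criterion R-R intervals (HR derived
#'   by the 16-beat moving average downstream); `"hr"` writes the criterion
#'   as a 1 Hz BPM stream directly.
#' @param age_mean,age_sd,female_p,bmi_mean,bmi_sd,wrist_mean,wrist_sd
#'   metadata distributions.
#' @param fitzpatrick_probs,indication_probs sampling weights.
#' @param profile named list of [truth_profile()] overrides applied to every
#'   participant (participant-level variation is added on top).
#' @param offset_choices integer clock offsets sampled uniformly.
#' @param bias_bpm,bias_sd_between mean wearable bias and its
#'   between-participant SD.
#' @param noise_sd_rest_bpm,motion_noise_coupling_bpm_per_g noise model.
#' @param dropout_prob_rest,dropout_motion_coupling_per_g dropout model.
#' @param zero_fill,constant_fill_bpm dropout emission policy.
#' @param signal_decay_start_s,decay_noise_multiplier optional late decay.
#' @param samplerate_bug_n number of participants (taken from the end of the
#'   cohort, emulating a firmware regression in late devices) whose stream
#'   degrades to `samplerate_bug_rate_hz` from their sleep onset.
#' @param samplerate_bug_rate_hz degraded rate, default one sample per minute.
#' @param comfort_wearable_mean,comfort_criterion_mean,comfort_item_sd,
#'   comfort_n_items Likert questionnaire generator.
#' @return A list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(duration_s = 86400,
                            criterion_source = c("rr", "hr"),
                            age_mean = 13.2, age_sd = 3.6, female_p = 0.45,
                            bmi_mean = 19.9, bmi_sd = 3.7,
                            wrist_mean = 15.4, wrist_sd = 1.7,
                            fitzpatrick_probs = c(I = 0, II = 0.34, III = 0.45,
                                                  IV = 0.14, V = 0.07, VI = 0),
                            indication_probs = c(CHD = 0.36, arrhythmia = 0.45,
                                                 symptoms = 0.19),
                            profile = list(),
                            offset_choices = -60:60,
                            bias_bpm = -1.4, bias_sd_between = 0.5,
                            noise_sd_rest_bpm = 3.5,
                            motion_noise_coupling_bpm_per_g = 30,
                            dropout_prob_rest = 0.025,
                            dropout_motion_coupling_per_g = 0,
                            zero_fill = TRUE, constant_fill_bpm = NULL,
                            signal_decay_start_s = NULL,
                            decay_noise_multiplier = 1,
                            samplerate_bug_n = 0,
                            samplerate_bug_rate_hz = 1 / 60,
                            comfort_wearable_mean = 3.8,
                            comfort_criterion_mean = 2.6,
                            comfort_item_sd = 0.7,
                            comfort_n_items = 6) {
  s <- as.list(environment())
  s$criterion_source <- match.arg(criterion_source)
  class(s) <- "cohort_scenario"
  s
}

participant_seed <- function(seed, i) (as.integer(seed) + i * 7919L) %% 2147483647L

sample_meta <- function(id, scenario, pseed) {
  with_seed(pseed + 10L, {
    repeat {
      age <- stats::rnorm(1, scenario$age_mean, scenario$age_sd)
      if (age >= 6 && age <= 18) break
    }
    age <- round(age, 1)
    sex <- if (stats::runif(1) < scenario$female_p) "female" else "male"
    height <- round(min(max(0.75 + 0.065 * age + stats::rnorm(1, 0, 0.07), 1.0), 2.0), 2)
    repeat {
      bmi <- stats::rnorm(1, scenario$bmi_mean, scenario$bmi_sd)
      if (bmi >= 13 && bmi <= 35) break
    }
    weight <- round(bmi * height^2, 1)
    wrist <- round(stats::rnorm(1, scenario$wrist_mean, scenario$wrist_sd), 1)
    fp <- scenario$fitzpatrick_probs
    ip <- scenario$indication_probs
    validate_meta(list(
      id = id, age_years = age, sex = sex, height_m = height,
      weight_kg = weight, bmi_kg_m2 = round(weight / height^2, 2),
      wrist_circumference_cm = wrist,
      fitzpatrick = sample(names(fp), 1, prob = fp),
      indication = sample(names(ip), 1, prob = ip),
      recording_start = "2024-03-01T10:00:00+01:00",
      duration_s = scenario$duration_s,
      accel_scale_divisor = 512))
  })
}

sample_profile <- function(meta, scenario, pseed) {
  dur <- scenario$duration_s
  with_seed(pseed + 11L, {
    awake <- 110 - 2.4 * meta$age_years + stats::rnorm(1, 0, 4)
    sleep <- awake - stats::runif(1, 14, 22)
    onset <- min(45000 + stats::rnorm(1, 0, 1800), dur * 2)
    wake <- onset + 32400 + stats::rnorm(1, 0, 1800)
    args <- list(duration_s = dur,
                 base_hr_awake_bpm = awake, base_hr_sleep_bpm = sleep,
                 sleep_onset_s = onset, wake_s = wake,
                 n_activity_bouts = sample(6:12, 1),
                 seed = pseed)
    args[names(scenario$profile)] <- scenario$profile
    do.call(truth_profile, args)
  })
}

sample_error_model <- function(scenario, pseed, bug, sleep_onset_s) {
  with_seed(pseed + 12L, {
    wearable_error_model(
      clock_offset_s = sample(scenario$offset_choices, 1),
      bias_bpm = scenario$bias_bpm + stats::rnorm(1, 0, scenario$bias_sd_between),
      noise_sd_rest_bpm = scenario$noise_sd_rest_bpm,
      motion_noise_coupling_bpm_per_g = scenario$motion_noise_coupling_bpm_per_g,
      dropout_prob_rest = scenario$dropout_prob_rest,
      dropout_motion_coupling_per_g = scenario$dropout_motion_coupling_per_g,
      zero_fill = scenario$zero_fill,
      constant_fill_bpm = scenario$constant_fill_bpm,
      signal_decay_start_s = scenario$signal_decay_start_s,
      decay_noise_multiplier = scenario$decay_noise_multiplier,
      samplerate_bug = if (bug)
        list(start_s = min(sleep_onset_s, scenario$duration_s - 3700),
             degraded_rate_hz = scenario$samplerate_bug_rate_hz) else NULL)
  })
}

gen_questionnaire <- function(scenario, pseed) {
  with_seed(pseed + 20L, {
    items <- paste0("q", seq_len(scenario$comfort_n_items))
    one <- function(device, mu) {
      sc <- pmin(pmax(round(mu + stats::rnorm(length(items), 0, scenario$comfort_item_sd)), 1), 5)
      row <- data.frame(device = device, wear_time_h = round(scenario$duration_s / 3600, 1))
      row[items] <- as.list(sc)
      row
    }
    validate_questionnaire(rbind(one("criterion", scenario$comfort_criterion_mean),
                                 one("wearable_wrist", scenario$comfort_wearable_mean)))
  })
}

## Generate one participant fully in memory (no disk writes); used by both
## gen_cohort() and the simulation studies in the test-suite/acceptance code.
gen_participant <- function(id, scenario, pseed, bug = FALSE) {
  meta <- sample_meta(id, scenario, pseed)
  profile <- sample_profile(meta, scenario, pseed)
  model <- sample_error_model(scenario, pseed, bug, profile$sleep_onset_s)
  truth <- gen_truth_hr(profile)
  accel <- gen_accel(profile)
  wearable <- corrupt_wearable(truth$hr, accel, model, seed = pseed + 13L)
  diary <- if (profile$sleep_onset_s < profile$duration_s) {
    validate_diary(data.frame(
      sleep_onset_s = round(profile$sleep_onset_s / 60) * 60,
      wake_s = round(min(profile$wake_s, profile$duration_s) / 60) * 60,
      notes = "bedtime"))
  } else NULL
  list(meta = meta, profile = profile, model = model, truth = truth,
       accel = accel, wearable = wearable, diary = diary,
       questionnaire = gen_questionnaire(scenario, pseed))
}

#' Generate and write a synthetic cohort
#'
#' Writes one directory per participant in the layout read by
#' [read_participant()], plus `ledger.csv` recording every injected truth
#' parameter (clock offset, bias, noise, dropout probability, sample-rate
#' defect flag), so downstream estimates can be compared to ground truth.
#' The same seed regenerates a byte-identical cohort; each participant draws
#' from its own substream, so adding participants never perturbs earlier ones.
#'
#' @param n_participants cohort size.
#' @param scenario a [cohort_scenario()].
#' @param seed master seed.
#' @param out_dir output directory (refused if it already contains a cohort,
#'   unless `overwrite = TRUE`).
#' @param overwrite replace an existing cohort directory.
#' @return Invisibly, the ledger `data.frame` (also written to
#'   `ledger.csv`).
#' @export
gen_cohort <- function(n_participants, scenario = cohort_scenario(), seed = 1,
                       out_dir, overwrite = FALSE) {
  stopifnot(inherits(scenario, "cohort_scenario"), n_participants >= 1)
  if (file.exists(file.path(out_dir, "ledger.csv")) && !overwrite)
    stop(out_dir, " already holds a cohort; use overwrite = TRUE to replace it")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ledger <- vector("list", n_participants)
  bug_ids <- if (scenario$samplerate_bug_n > 0)
    seq(n_participants - scenario$samplerate_bug_n + 1, n_participants) else integer(0)
  for (i in seq_len(n_participants)) {
    id <- sprintf("P%02d", i)
    pseed <- participant_seed(seed, i)
    p <- gen_participant(id, scenario, pseed, bug = i %in% bug_ids)
    pdir <- file.path(out_dir, id)
    dir.create(pdir, showWarnings = FALSE)
    write_meta(p$meta, file.path(pdir, "meta.yaml"))
    if (scenario$criterion_source == "rr") {
      write_rr_csv(p$truth$rr, file.path(pdir, "criterion_rr.csv"))
    } else {
      write_hr_csv(p$truth$hr, file.path(pdir, "criterion_hr.csv"))
    }
    write_hr_csv(p$wearable, file.path(pdir, "wearable_hr.csv"))
    write_accel_csv(p$accel, file.path(pdir, "wearable_accel.csv"))
    if (!is.null(p$diary)) write_diary(p$diary, file.path(pdir, "diary.csv"))
    write_questionnaire(p$questionnaire, file.path(pdir, "questionnaire.csv"))
    ledger[[i]] <- data.frame(
      id = id, seed = pseed,
      clock_offset_s = p$model$clock_offset_s,
      bias_bpm = p$model$bias_bpm,
      noise_sd_rest_bpm = p$model$noise_sd_rest_bpm,
      motion_noise_coupling_bpm_per_g = p$model$motion_noise_coupling_bpm_per_g,
      dropout_prob_rest = p$model$dropout_prob_rest,
      samplerate_bug = !is.null(p$model$samplerate_bug),
      sleep_onset_s = p$profile$sleep_onset_s,
      wake_s = p$profile$wake_s,
      base_hr_awake_bpm = p$profile$base_hr_awake_bpm,
      base_hr_sleep_bpm = p$profile$base_hr_sleep_bpm)
  }
  ledger <- do.call(rbind, ledger)
  utils::write.csv(ledger, file.path(out_dir, "ledger.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(ledger)
}
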
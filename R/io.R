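## On-disk layout: one directory per participant, holding
##   meta.yaml            participant metadata (+ ISO-8601 recording_start)
##   criterion_rr.csv     beat_time,rr_ms            (or criterion_hr.csv t,bpm)
##   wearable_hr.csv      t,bpm  (empty field = missing; literal 0 preserved)
##   wearable_accel.csv   t,acc_x,acc_y,acc_z
##   diary.csv            sleep_onset_s,wake_s,notes
##   questionnaire.csv    device,wear_time_h,q1..qK
## All CSVs are RFC-4180, UTF-8, header row mandatory. Timestamps are numeric
## seconds since the recording start named in meta.yaml, which keeps read/write
## round trips field-exact and device clock offsets explicit.

INDICATIONS <- c("CHD", "arrhythmia", "symptoms")
FITZPATRICK <- c("I", "II", "III", "IV", "V", "VI")
DEVICES <- c("criterion", "wearable_wrist", "wearable_shirt")

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  x
}

num_col <- function(x, col, path, allow_na = FALSE) {
  v <- x[[col]]
  if (is.character(v)) {
    v[trimws(v) == ""] <- NA
    v2 <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(v2))
    if (length(bad))
      stop(sprintf("%s: cannot parse column '%s' as a number at data row %d (value '%s')",
                   path, col, bad[1], v[bad[1]]))
    v <- v2
  }
  if (!allow_na && any(is.na(v)))
    stop(sprintf("%s: column '%s' has missing values", path, col))
  as.numeric(v)
}

#' Read a heart-rate CSV stream
#'
#' The dialect declares the column names and the missing-value token (default:
#' empty field). Literal zeros are kept as the number 0, not converted to
#' missing, because zero occurrences are counted as underdetected data later
#' and that distinction must survive I/O.
#'
#' @param path CSV file path.
#' @param dialect list with elements `time_col`, `bpm_col`, `missing` (token).
#' @param nominal_rate_hz declared sampling rate recorded on the series.
#' @return An [hr_series()].
#' @export
read_hr_csv <- function(path, dialect = list(time_col = "t", bpm_col = "bpm",
                                             missing = ""),
                        nominal_rate_hz = 1) {
  x <- read_csv_strict(path, c(dialect$time_col, dialect$bpm_col))
  bpm_raw <- x[[dialect$bpm_col]]
  if (is.character(bpm_raw)) {
    bpm_raw[trimws(bpm_raw) == dialect$missing] <- NA
    x[[dialect$bpm_col]] <- bpm_raw
  }
  t <- num_col(x, dialect$time_col, path)
  bpm <- num_col(x, dialect$bpm_col, path, allow_na = TRUE)
  hr_series(t, bpm, nominal_rate_hz = nominal_rate_hz)
}

#' Write a heart-rate CSV stream
#'
#' Inverse of [read_hr_csv()]; missing samples are written as empty fields.
#' @param x an [hr_series()].
#' @param path output path.
#' @export
write_hr_csv <- function(x, path) {
  stopifnot(inherits(x, "hr_series"))
  utils::write.csv(data.frame(t = x$t, bpm = x$bpm), path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read an R-R interval CSV (columns `beat_time`, `rr_ms`)
#' @param path CSV file path.
#' @return An [rr_series()].
#' @export
read_rr_csv <- function(path) {
  x <- read_csv_strict(path, c("beat_time", "rr_ms"))
  rr_series(num_col(x, "beat_time", path), num_col(x, "rr_ms", path))
}

#' @rdname read_rr_csv
#' @param x an [rr_series()].
#' @export
write_rr_csv <- function(x, path) {
  stopifnot(inherits(x, "rr_series"))
  utils::write.csv(data.frame(beat_time = x$beat_time, rr_ms = x$rr_ms), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a triaxial accelerometry CSV (columns `t`, `acc_x`, `acc_y`, `acc_z`)
#'
#' Values are stored untransformed; `scale_divisor` (counts per g; 512 for
#' count data, 1 for data already in g) is recorded for later magnitude
#' computation.
#' @param path CSV file path.
#' @param scale_divisor counts per g.
#' @return An [accel_series()].
#' @export
read_accel_csv <- function(path, scale_divisor = 512) {
  x <- read_csv_strict(path, c("t", "acc_x", "acc_y", "acc_z"))
  accel_series(num_col(x, "t", path),
               num_col(x, "acc_x", path), num_col(x, "acc_y", path),
               num_col(x, "acc_z", path), scale_divisor = scale_divisor)
}

#' @rdname read_accel_csv
#' @param x an [accel_series()].
#' @export
write_accel_csv <- function(x, path) {
  stopifnot(inherits(x, "accel_series"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sleep diary CSV (columns `sleep_onset_s`, `wake_s`, `notes`)
#'
#' One row per sleep episode, in seconds since recording start.
#' @param path CSV file path.
#' @param span_s optional recording span; episodes must fall inside it.
#' @return A `data.frame` of class `diary`.
#' @export
read_diary <- function(path, span_s = NULL) {
  x <- read_csv_strict(path, c("sleep_onset_s", "wake_s"))
  d <- data.frame(sleep_onset_s = num_col(x, "sleep_onset_s", path),
                  wake_s = num_col(x, "wake_s", path),
                  notes = if ("notes" %in% names(x)) as.character(x$notes) else "")
  validate_diary(d, span_s)
}

validate_diary <- function(d, span_s = NULL) {
  if (any(d$sleep_onset_s >= d$wake_s))
    stop("diary: sleep_onset_s must precede wake_s in every episode")
  if (!is.null(span_s) && any(d$sleep_onset_s < 0 | d$wake_s > span_s))
    stop("diary: sleep episode outside the recording span")
  class(d) <- c("diary", "data.frame")
  d
}

#' @rdname read_diary
#' @param d a diary data.frame.
#' @export
write_diary <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read participant metadata from YAML
#'
#' Required fields: `id`, `age_years`, `sex`, `height_m`, `weight_kg`,
#' `bmi_kg_m2`, `indication`; optional: `wrist_circumference_cm`,
#' `fitzpatrick`, `recording_start` (ISO-8601), `duration_s`. BMI must agree
#' with height and weight within 1%, age must lie in \[6, 18\] years and the
#' indication in `{CHD, arrhythmia, symptoms}`.
#' @param path YAML file path.
#' @return A list of class `participant_meta`.
#' @export
read_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- yaml::read_yaml(path)
  validate_meta(m, path)
}

validate_meta <- function(m, path = "<meta>") {
  req <- c("id", "age_years", "sex", "height_m", "weight_kg", "bmi_kg_m2",
           "indication")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop(sprintf("%s: missing metadata field(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (m$age_years < 6 || m$age_years > 18)
    stop(sprintf("%s: age_years must be within [6, 18], got %s", path, m$age_years))
  bmi_hw <- m$weight_kg / m$height_m^2
  if (abs(m$bmi_kg_m2 - bmi_hw) / bmi_hw > 0.01)
    stop(sprintf("%s: bmi_kg_m2 (%.2f) inconsistent with height/weight (%.2f) by more than 1%%",
                 path, m$bmi_kg_m2, bmi_hw))
  if (!m$indication %in% INDICATIONS)
    stop(sprintf("%s: indication must be one of {%s}, got '%s'", path,
                 paste(INDICATIONS, collapse = ", "), m$indication))
  if (!is.null(m$fitzpatrick) && !m$fitzpatrick %in% FITZPATRICK)
    stop(sprintf("%s: fitzpatrick must be one of I..VI", path))
  class(m) <- "participant_meta"
  m
}

#' @rdname read_meta
#' @param m a `participant_meta` list.
#' @export
write_meta <- function(m, path) {
  yaml::write_yaml(unclass(m), path)
  invisible(path)
}

#' Read a questionnaire CSV
#'
#' Wide format: one row per device (`criterion`, `wearable_wrist`,
#' `wearable_shirt`), a `wear_time_h` column and item columns `q1`, `q2`, ...
#' holding 5-point Likert scores. Every score must lie in 1..5.
#' @param path CSV file path.
#' @return A `data.frame` of class `questionnaire`.
#' @export
read_questionnaire <- function(path) {
  x <- read_csv_strict(path, c("device", "wear_time_h"))
  validate_questionnaire(x, path)
}

validate_questionnaire <- function(x, path = "<questionnaire>") {
  items <- grep("^q[0-9]+$", names(x), value = TRUE)
  if (!length(items)) stop(path, ": no item columns (q1, q2, ...) found")
  if (!all(x$device %in% DEVICES))
    stop(sprintf("%s: device must be one of {%s}", path,
                 paste(DEVICES, collapse = ", ")))
  for (it in items) {
    v <- x[[it]]
    bad <- which(!is.na(v) & (v < 1 | v > 5 | v != round(v)))
    if (length(bad))
      stop(sprintf("%s: item %s has a score outside 1..5 at data row %d",
                   path, it, bad[1]))
  }
  attr(x, "items") <- items
  class(x) <- c("questionnaire", "data.frame")
  x
}

#' @rdname read_questionnaire
#' @param x a questionnaire data.frame.
#' @export
write_questionnaire <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one participant directory
#'
#' Expects the layout written by [gen_cohort()]: `meta.yaml`, a criterion
#' stream (`criterion_rr.csv` or `criterion_hr.csv`), `wearable_hr.csv`,
#' `wearable_accel.csv`, and optionally `diary.csv` and `questionnaire.csv`.
#'
#' @param dir participant directory.
#' @return A list with elements `meta`, `rr` (or NULL), `criterion_hr` (or
#'   NULL), `wearable`, `accel`, `diary`, `questionnaire`.
#' @export
read_participant <- function(dir) {
  meta <- read_meta(file.path(dir, "meta.yaml"))
  rr <- NULL; chr <- NULL
  if (file.exists(file.path(dir, "criterion_rr.csv"))) {
    rr <- read_rr_csv(file.path(dir, "criterion_rr.csv"))
    attr(rr, "participant") <- meta$id
  } else if (file.exists(file.path(dir, "criterion_hr.csv"))) {
    chr <- read_hr_csv(file.path(dir, "criterion_hr.csv"))
    attr(chr, "participant") <- meta$id
  } else stop(dir, ": no criterion stream (criterion_rr.csv or criterion_hr.csv)")
  wearable <- read_hr_csv(file.path(dir, "wearable_hr.csv"))
  attr(wearable, "participant") <- meta$id
  accel <- read_accel_csv(file.path(dir, "wearable_accel.csv"),
                          scale_divisor = if (is.null(meta$accel_scale_divisor)) 512
                                          else meta$accel_scale_divisor)
  attr(accel, "participant") <- meta$id
  span <- if (!is.null(meta$duration_s)) meta$duration_s else NULL
  diary <- if (file.exists(file.path(dir, "diary.csv")))
    read_diary(file.path(dir, "diary.csv"), span_s = span) else NULL
  quest <- if (file.exists(file.path(dir, "questionnaire.csv")))
    read_questionnaire(file.path(dir, "questionnaire.csv")) else NULL
  list(meta = meta, rr = rr, criterion_hr = chr, wearable = wearable,
       accel = accel, diary = diary, questionnaire = quest)
}
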
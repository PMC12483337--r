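## Lightweight time-series containers. All are data.frames with a class tag and
## a few attributes; time is always numeric seconds since the participant's
## recording start, so inter-device offsets stay explicit.

#' Heart-rate series
#'
#' A timestamped heart-rate stream in beats per minute. Missing samples are
#' `NA`; literal zeros are preserved on construction because several wearables
#' emit 0 for undetected beats, and the zero-counting missingness rules need to
#' see them (a true HR of 0 is out of physiological range anyway).
#'
#' @param t numeric, seconds since recording start, strictly increasing.
#' @param bpm numeric heart rate; `NA` for missing, values in `[0, 300)`.
#' @param nominal_rate_hz declared sampling rate (`NA` for beat-aligned series).
#' @param participant optional participant id carried as an attribute.
#' @return A `data.frame` of class `hr_series` with columns `t`, `bpm`.
#' @export
hr_series <- function(t, bpm, nominal_rate_hz = 1, participant = NULL) {
  t <- as.numeric(t)
  bpm <- as.numeric(bpm)
  if (length(t) != length(bpm)) stop("t and bpm must have equal length")
  check_time(t)
  bad <- which(!is.na(bpm) & (bpm < 0 | bpm >= 300 | !is.finite(bpm)))
  if (length(bad)) {
    stop(sprintf("bpm out of range [0, 300) at row %d (value %s)",
                 bad[1], format(bpm[bad[1]])))
  }
  x <- data.frame(t = t, bpm = bpm)
  class(x) <- c("hr_series", "data.frame")
  attr(x, "nominal_rate_hz") <- nominal_rate_hz
  attr(x, "participant") <- participant
  x
}

#' R-R interval series
#'
#' Successive ECG beat-to-beat intervals, the criterion device's native output.
#' `rr_ms[i]` is the interval ending at `beat_time[i]`.
#'
#' @param beat_time numeric seconds since recording start, strictly increasing.
#' @param rr_ms positive finite interval lengths in milliseconds.
#' @param participant optional participant id.
#' @return A `data.frame` of class `rr_series`.
#' @export
rr_series <- function(beat_time, rr_ms, participant = NULL) {
  beat_time <- as.numeric(beat_time)
  rr_ms <- as.numeric(rr_ms)
  if (length(beat_time) != length(rr_ms)) stop("beat_time and rr_ms must have equal length")
  check_time(beat_time, name = "beat_time")
  bad <- which(!is.finite(rr_ms) | rr_ms <= 0)
  if (length(bad)) stop(sprintf("rr_ms must be finite and > 0 (row %d)", bad[1]))
  x <- data.frame(beat_time = beat_time, rr_ms = rr_ms)
  class(x) <- c("rr_series", "data.frame")
  attr(x, "participant") <- participant
  x
}

#' Triaxial accelerometry series
#'
#' Raw triaxial acceleration, either in counts (with `scale_divisor` counts per
#' g, 512 for typical wrist devices) or already in g (`scale_divisor = 1`).
#' Values are stored untransformed; scaling happens in [accel_magnitude()].
#'
#' @param t numeric seconds since recording start, strictly increasing.
#' @param acc_x,acc_y,acc_z finite axis values.
#' @param scale_divisor counts per g; must be > 0.
#' @param participant optional participant id.
#' @return A `data.frame` of class `accel_series`.
#' @export
accel_series <- function(t, acc_x, acc_y, acc_z, scale_divisor = 512,
                         participant = NULL) {
  t <- as.numeric(t)
  n <- length(t)
  if (length(acc_x) != n || length(acc_y) != n || length(acc_z) != n)
    stop("all axes must match the length of t")
  check_time(t)
  if (!is.finite(scale_divisor) || scale_divisor <= 0)
    stop("scale_divisor must be > 0")
  for (ax in list(acc_x = acc_x, acc_y = acc_y, acc_z = acc_z)) {
    if (any(!is.finite(ax))) stop("accelerometer axes must be finite")
  }
  x <- data.frame(t = t, acc_x = as.numeric(acc_x), acc_y = as.numeric(acc_y),
                  acc_z = as.numeric(acc_z))
  class(x) <- c("accel_series", "data.frame")
  attr(x, "scale_divisor") <- scale_divisor
  attr(x, "participant") <- participant
  x
}

check_time <- function(t, name = "t") {
  if (any(!is.finite(t))) stop(sprintf("%s must be finite", name))
  if (length(t) > 1) {
    d <- diff(t)
    bad <- which(d <= 0)
    if (length(bad)) {
      stop(sprintf("%s must be strictly increasing (violation between rows %d and %d)",
                   name, bad[1], bad[1] + 1L))
    }
  }
  invisible(TRUE)
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> %d samples, %.0f s span, nominal %s Hz, %d missing\n",
              nrow(x), if (nrow(x)) diff(range(x$t)) else 0,
              format(attr(x, "nominal_rate_hz")), sum(is.na(x$bpm))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, %.0f s span, mean RR %.1f ms\n",
              nrow(x), if (nrow(x)) diff(range(x$beat_time)) else 0,
              mean(x$rr_ms)))
  invisible(x)
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> %d samples, scale_divisor %s\n",
              nrow(x), format(attr(x, "scale_divisor"))))
  invisible(x)
}

## Evaluate a block with a given RNG seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
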
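## Criterion R-R to HR conversion, cross-correlation clock synchronization,
## interpolation of the wearable onto criterion timestamps, and missing-data
## classification (underdetected = wearable side, erroneous = criterion side).

#' Heart rate from R-R intervals by a trailing moving average
#'
#' At each beat `i >= window_beats`, HR is `60000 / mean(rr_ms)` over the
#' window of `window_beats` intervals ending at beat `i` (the current beat's
#' interval included), timestamped at that beat. The 16-beat default smooths
#' beat-level artifacts and noise in ambulatory ECG. The first
#' `window_beats - 1` beats emit no sample.
#'
#' @param rr an [rr_series()].
#' @param window_beats moving-average window length in beats.
#' @return A beat-aligned [hr_series()] (`nominal_rate_hz = NA`).
#' @export
hr_from_rr <- function(rr, window_beats = 16) {
  stopifnot(inherits(rr, "rr_series"), window_beats >= 1)
  n <- nrow(rr)
  if (n < window_beats) {
    warning(sprintf("series of %d beats is shorter than the %d-beat window; empty output",
                    n, window_beats))
    return(hr_series(numeric(0), numeric(0), nominal_rate_hz = NA,
                     participant = attr(rr, "participant")))
  }
  cs <- c(0, cumsum(rr$rr_ms))
  win_mean <- (cs[(window_beats + 1):(n + 1)] - cs[1:(n - window_beats + 1)]) / window_beats
  hr_series(rr$beat_time[window_beats:n], 60000 / win_mean,
            nominal_rate_hz = NA, participant = attr(rr, "participant"))
}

## Resample a (possibly beat-aligned) HR series onto the integer-second grid
## by linear interpolation across non-missing samples; zeros count as missing.
grid_1hz <- function(x) {
  ok <- !is.na(x$bpm) & x$bpm > 0
  if (sum(ok) < 2) stop("series has fewer than 2 usable samples")
  t <- seq(ceiling(min(x$t[ok])), floor(max(x$t[ok])))
  list(t = t, bpm = stats::approx(x$t[ok], x$bpm[ok], xout = t)$y)
}

#' Estimate the inter-device clock offset by cross-correlation
#'
#' Both series are resampled to a common 1 s grid; the offset is the integer
#' lag in `[-max_lag_s, max_lag_s]` maximizing the Pearson correlation
#' between overlapping non-missing samples. A positive offset means the
#' wearable clock runs ahead: `wearable(t)` matches `criterion(t - offset)`.
#' Ties are broken by the smallest `|lag|`, then by the negative lag.
#'
#' @param criterion,wearable [hr_series()] objects.
#' @param max_lag_s search half-width in seconds.
#' @return A list of class `sync_result` with `offset_s`, `peak_correlation`,
#'   `n_overlap`, and the full `lags`/`correlation` curve.
#' @export
estimate_offset <- function(criterion, wearable, max_lag_s = 60) {
  stopifnot(inherits(criterion, "hr_series"), inherits(wearable, "hr_series"))
  gc_ <- grid_1hz(criterion)
  gw <- grid_1hz(wearable)
  lags <- seq(-max_lag_s, max_lag_s)
  cors <- numeric(length(lags))
  n_ov <- integer(length(lags))
  for (k in seq_along(lags)) {
    lag <- lags[k]
    ## correlate criterion(t) with wearable(t + lag)
    t0 <- max(gc_$t[1], gw$t[1] - lag)
    t1 <- min(gc_$t[length(gc_$t)], gw$t[length(gw$t)] - lag)
    if (t1 - t0 + 1 < 300)
      stop(sprintf("insufficient overlap (%d s) at lag %d; need >= 300 s",
                   max(t1 - t0 + 1, 0), lag))
    ci <- gc_$bpm[(t0 - gc_$t[1] + 1):(t1 - gc_$t[1] + 1)]
    wi <- gw$bpm[(t0 + lag - gw$t[1] + 1):(t1 + lag - gw$t[1] + 1)]
    ok <- !is.na(ci) & !is.na(wi)
    n_ov[k] <- sum(ok)
    if (n_ov[k] < 300) stop("insufficient non-missing overlap at lag ", lag)
    if (stats::sd(ci[ok]) == 0 || stats::sd(wi[ok]) == 0)
      stop("correlation undefined: a series is constant over the overlap")
    cors[k] <- stats::cor(ci[ok], wi[ok])
  }
  best <- which(cors == max(cors))
  if (length(best) > 1) {  # smallest |lag|, then negative
    best <- best[order(abs(lags[best]), lags[best])][1]
  }
  structure(list(offset_s = lags[best], peak_correlation = cors[best],
                 n_overlap = n_ov[best], lags = lags, correlation = cors),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> offset %+d s, peak correlation %.4f over %d samples\n",
              x$offset_s, x$peak_correlation, x$n_overlap))
  invisible(x)
}

#' Interpolate the wearable onto criterion timestamps
#'
#' After shifting the wearable clock back by the estimated offset, wearable
#' BPM is linearly interpolated onto each criterion timestamp. Zero-valued
#' wearable samples are treated as missing before interpolation. Gaps between
#' usable wearable samples longer than `max_bridge_gap_s` are not bridged:
#' criterion rows inside them are marked `underdetected`, as are rows outside
#' the wearable's span. Rows whose criterion value is itself missing are
#' marked `erroneous` (criterion-device failure) and are excluded from every
#' downstream statistic.
#'
#' @param wearable,criterion [hr_series()] objects.
#' @param offset_s clock offset from [estimate_offset()].
#' @param max_bridge_gap_s longest gap linear interpolation may cross.
#' @return A `data.frame` of class `paired_series` with columns `t`,
#'   `criterion_bpm`, `wearable_bpm`, `missing_cause`
#'   (`"none" | "underdetected" | "erroneous"`).
#' @export
resample_to_criterion <- function(wearable, criterion, offset_s = 0,
                                  max_bridge_gap_s = 60) {
  stopifnot(inherits(wearable, "hr_series"), inherits(criterion, "hr_series"))
  wt <- wearable$t - offset_s
  ok <- !is.na(wearable$bpm) & wearable$bpm > 0
  if (!any(ok)) stop("wearable series has no usable samples")
  wt_ok <- wt[ok]; wb_ok <- wearable$bpm[ok]
  ct <- criterion$t
  if (max(wt_ok) < min(ct) || min(wt_ok) > max(ct))
    stop("no overlap between wearable and criterion after offset correction")

  wearable_bpm <- rep(NA_real_, length(ct))
  cause <- rep("underdetected", length(ct))
  i <- findInterval(ct, wt_ok)
  ## exact hits (within numerical tolerance) pass through unchanged
  exact <- i >= 1 & abs(ct - wt_ok[pmax(i, 1L)]) < 1e-9
  wearable_bpm[exact] <- wb_ok[pmax(i, 1L)][exact]
  cause[exact] <- "none"
  inside <- !exact & i >= 1 & i < length(wt_ok)
  if (any(inside)) {
    gap <- wt_ok[i[inside] + 1L] - wt_ok[i[inside]]
    bridge <- gap <= max_bridge_gap_s
    idx <- which(inside)[bridge]
    if (length(idx)) {
      ii <- i[idx]
      f <- (ct[idx] - wt_ok[ii]) / (wt_ok[ii + 1L] - wt_ok[ii])
      wearable_bpm[idx] <- (1 - f) * wb_ok[ii] + f * wb_ok[ii + 1L]
      cause[idx] <- "none"
    }
  }
  err <- is.na(criterion$bpm) | criterion$bpm <= 0
  cause[err] <- "erroneous"
  wearable_bpm[err] <- NA_real_
  crit_bpm <- criterion$bpm
  crit_bpm[err] <- NA_real_
  out <- data.frame(t = ct, criterion_bpm = crit_bpm,
                    wearable_bpm = wearable_bpm, missing_cause = cause)
  class(out) <- c("paired_series", "data.frame")
  attr(out, "offset_s") <- offset_s
  attr(out, "participant") <- attr(criterion, "participant")
  out
}

#' Classify missing data into underdetected and erroneous fractions
#'
#' Underdetected data (wearable side) are missing or zero-valued samples of
#' the raw wearable stream, counted against the nominal expected sample count
#' over its span (so samples absent entirely — e.g. under a degraded sample
#' rate — are counted too). Erroneous data (criterion side) are missing
#' criterion rows of the paired series. A sample-rate anomaly is flagged when
#' the raw wearable inter-sample interval exceeds twice the nominal period
#' over a contiguous run of at least one hour.
#'
#' @param paired a [resample_to_criterion()] result.
#' @param wearable_raw the raw wearable [hr_series()] (pre-interpolation).
#' @param nominal_rate_hz declared wearable rate; defaults to the series
#'   attribute.
#' @return A list of class `missingness_report`: `pct_underdetected`,
#'   `pct_erroneous`, `n_zero`, `n_absent`, `n_na`, `expected_n`,
#'   `samplerate_anomaly`.
#' @export
classify_missing <- function(paired, wearable_raw,
                             nominal_rate_hz = attr(wearable_raw, "nominal_rate_hz")) {
  stopifnot(inherits(paired, "paired_series"), inherits(wearable_raw, "hr_series"))
  if (is.null(nominal_rate_hz) || is.na(nominal_rate_hz))
    stop("classify_missing needs a nominal sampling rate")
  span <- diff(range(wearable_raw$t))
  expected_n <- floor(span * nominal_rate_hz) + 1L
  n_zero <- sum(!is.na(wearable_raw$bpm) & wearable_raw$bpm == 0)
  n_na <- sum(is.na(wearable_raw$bpm))
  n_absent <- max(expected_n - nrow(wearable_raw), 0L)
  pct_under <- 100 * (n_zero + n_na + n_absent) / expected_n
  pct_err <- 100 * sum(paired$missing_cause == "erroneous") / nrow(paired)

  dt <- diff(wearable_raw$t)
  slow <- dt > 2 / nominal_rate_hz
  anomaly <- FALSE
  if (any(slow)) {
    r <- rle(slow)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      if (sum(dt[starts[j]:ends[j]]) >= 3600) { anomaly <- TRUE; break }
    }
  }
  structure(list(pct_underdetected = pct_under, pct_erroneous = pct_err,
                 n_zero = n_zero, n_na = n_na, n_absent = n_absent,
                 expected_n = expected_n, samplerate_anomaly = anomaly),
            class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat(sprintf("<missingness_report> underdetected %.2f%% (zeros %d, NA %d, absent %d of %d expected), erroneous %.2f%%%s\n",
              x$pct_underdetected, x$n_zero, x$n_na, x$n_absent, x$expected_n,
              x$pct_erroneous,
              if (x$samplerate_anomaly) ", SAMPLE-RATE ANOMALY" else ""))
  invisible(x)
}

#' Detect constant-fill runs in a wearable stream
#'
#' Some devices hide missing data by repeating the last known heart rate or a
#' fixed fallback value (e.g. 70 BPM) instead of emitting gaps. This
#' diagnostic masks runs of exactly constant BPM lasting at least
#' `min_run_s`. It is off by default in the pipeline: such rows cannot be
#' proven missing, so they are flagged, not excluded, unless the caller asks.
#'
#' @param series an [hr_series()].
#' @param fill_bpm the device's documented fallback value (reported per run).
#' @param min_run_s minimum run duration to mask.
#' @return A logical mask along `series` rows; attribute `runs` holds a
#'   per-run summary (`start_s`, `end_s`, `value`, `is_fill_value`).
#' @export
detect_constant_fill <- function(series, fill_bpm = 70, min_run_s = 30) {
  stopifnot(inherits(series, "hr_series"))
  n <- nrow(series)
  mask <- rep(FALSE, n)
  if (n < 2) return(mask)
  key <- ifelse(is.na(series$bpm), NA_character_, format(series$bpm, digits = 12))
  r <- rle(key)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- list()
  for (j in seq_along(r$lengths)) {
    if (is.na(r$values[j]) || r$lengths[j] < 2) next
    dur <- series$t[ends[j]] - series$t[starts[j]]
    if (dur >= min_run_s) {
      mask[starts[j]:ends[j]] <- TRUE
      runs[[length(runs) + 1L]] <- data.frame(
        start_s = series$t[starts[j]], end_s = series$t[ends[j]],
        value = series$bpm[starts[j]],
        is_fill_value = isTRUE(all.equal(series$bpm[starts[j]], fill_bpm)))
    }
  }
  attr(mask, "runs") <- if (length(runs)) do.call(rbind, runs) else
    data.frame(start_s = numeric(0), end_s = numeric(0), value = numeric(0),
               is_fill_value = logical(0))
  mask
}
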
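## Synthetic 24-hour pediatric recordings with known ground truth.
##
## Truth heart rate = circadian wake/sleep baseline + activity-bout boosts +
## respiratory sinus arrhythmia + a slow Ornstein-Uhlenbeck heart-rate
## variability wander. The wearable observes this truth through a
## parameterized error model: clock offset, additive bias, rest noise,
## motion-coupled noise, dropout (optionally emitted as zeros or constant
## fill), second-half signal decay and an optional nighttime sample-rate
## defect. Every generated stream is traceable to a ledger entry.

#' Ground-truth profile for one synthetic participant
#'
#' Defaults describe a 24-hour free-living recording started mid-morning:
#' sleep onset about 12.5 h in (~22:30 for a 10:00 start), 9 h of sleep,
#' awake/sleep baselines in the pediatric range, 3 BPM respiratory sinus
#' arrhythmia at a 4 s breathing period, and a 5 BPM slow HR-variability
#' wander with a 30 s time constant.
#'
#' @param duration_s recording length in seconds.
#' @param base_hr_awake_bpm,base_hr_sleep_bpm circadian baselines (BPM);
#'   sleep must be below awake.
#' @param sleep_onset_s,wake_s sleep window bounds (seconds from start). An
#'   onset at or beyond `duration_s` means no sleep occurs in the window.
#' @param rsa_amplitude_bpm,rsa_period_s respiratory sinus arrhythmia.
#' @param hrv_wander_sd_bpm,hrv_wander_tau_s stationary SD and time constant
#'   of the slow Ornstein-Uhlenbeck HR wander.
#' @param n_activity_bouts number of movement bouts (placed while awake).
#' @param bout_duration_range_s,bout_hr_boost_range_bpm,bout_acc_range_g
#'   uniform ranges for bout length, HR boost and movement intensity.
#' @param rr_jitter_sd multiplicative log-normal beat-to-beat jitter SD.
#' @param rest_acc_noise_g accelerometer rest-noise floor (g per axis),
#'   reached during sleep.
#' @param wake_fidget_g additional mean movement intensity (g) while awake
#'   but outside activity bouts — children fidget even at rest, and this
#'   daytime micro-movement is what degrades optical heart-rate sensing
#'   during the day relative to sleep.
#' @param rest_acc_modulation_sd SD (log scale) of the slow modulation of the
#'   rest floor — how heterogeneous micro-movement is across the day.
#' @param seed RNG seed; all randomness of this participant flows from it
#'   through fixed substreams.
#' @return A list of class `truth_profile`.
#' @export
truth_profile <- function(duration_s = 86400,
                          base_hr_awake_bpm = 80,
                          base_hr_sleep_bpm = 62,
                          sleep_onset_s = 45000,
                          wake_s = 77400,
                          rsa_amplitude_bpm = 3,
                          rsa_period_s = 4,
                          hrv_wander_sd_bpm = 5,
                          hrv_wander_tau_s = 30,
                          n_activity_bouts = 8,
                          bout_duration_range_s = c(300, 1800),
                          bout_hr_boost_range_bpm = c(20, 60),
                          bout_acc_range_g = c(0.05, 0.4),
                          rr_jitter_sd = 0.02,
                          rest_acc_noise_g = 0.003,
                          wake_fidget_g = 0.075,
                          rest_acc_modulation_sd = 0.5,
                          seed = 1) {
  p <- as.list(environment())
  if (p$duration_s <= 0) stop("duration_s must be positive")
  if (p$base_hr_sleep_bpm >= p$base_hr_awake_bpm)
    stop("base_hr_sleep_bpm must be below base_hr_awake_bpm")
  if (p$sleep_onset_s >= p$wake_s) stop("sleep_onset_s must precede wake_s")
  if (any(p$bout_duration_range_s <= 0)) stop("bout durations must be positive")
  class(p) <- "truth_profile"
  p
}

#' Wearable error model
#'
#' Each nominal 1 Hz wearable sample observes
#' `truth(t - clock_offset_s) + bias + N(0, sd(t))` with
#' `sd(t) = (noise_sd_rest_bpm + motion_noise_coupling_bpm_per_g * g(t))`
#' times `decay_noise_multiplier` after `signal_decay_start_s`. Samples drop
#' out with probability `dropout_prob_rest + dropout_motion_coupling_per_g *
#' g(t)`; dropped samples are emitted as `NA`, as literal zeros
#' (`zero_fill`), or as the last known value / a constant
#' (`constant_fill_bpm`). `samplerate_bug = list(start_s, degraded_rate_hz)`
#' thins the stream after `start_s`, emulating a firmware defect that drops a
#' 1-per-second stream to 1-per-minute at night.
#'
#' @param clock_offset_s integer device clock offset in \[-60, 60\] seconds.
#' @param bias_bpm additive bias.
#' @param noise_sd_rest_bpm Gaussian noise SD at rest.
#' @param motion_noise_coupling_bpm_per_g extra noise SD per g of movement.
#' @param dropout_prob_rest per-sample dropout probability at rest.
#' @param dropout_motion_coupling_per_g extra dropout probability per g.
#' @param zero_fill emit dropped samples as literal 0 instead of `NA`.
#' @param constant_fill_bpm if non-NULL, dropped samples repeat the last
#'   known value (this constant is used before the first known value).
#' @param signal_decay_start_s,decay_noise_multiplier optional late-recording
#'   degradation (e.g. drying electrode gel on an ECG shirt).
#' @param samplerate_bug optional `list(start_s=, degraded_rate_hz=)`.
#' @return A list of class `wearable_error_model`.
#' @export
wearable_error_model <- function(clock_offset_s = 0,
                                 bias_bpm = 0,
                                 noise_sd_rest_bpm = 0,
                                 motion_noise_coupling_bpm_per_g = 0,
                                 dropout_prob_rest = 0,
                                 dropout_motion_coupling_per_g = 0,
                                 zero_fill = FALSE,
                                 constant_fill_bpm = NULL,
                                 signal_decay_start_s = NULL,
                                 decay_noise_multiplier = 1,
                                 samplerate_bug = NULL) {
  m <- as.list(environment())
  if (abs(m$clock_offset_s) > 60) stop("|clock_offset_s| must be <= 60")
  if (m$dropout_prob_rest < 0 || m$dropout_prob_rest > 1)
    stop("dropout_prob_rest must lie in [0, 1]")
  if (m$noise_sd_rest_bpm < 0 || m$motion_noise_coupling_bpm_per_g < 0)
    stop("noise parameters must be non-negative")
  if (!is.null(m$samplerate_bug) &&
      !all(c("start_s", "degraded_rate_hz") %in% names(m$samplerate_bug)))
    stop("samplerate_bug needs start_s and degraded_rate_hz")
  class(m) <- "wearable_error_model"
  m
}

## Ornstein-Uhlenbeck sample path on a 1 s grid, stationary SD `sd`.
ou_path <- function(n, sd, tau) {
  if (sd <= 0) return(rep(0, n))
  a <- exp(-1 / tau)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - a^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

## Activity bouts shared between HR and accelerometry: same seed substream, so
## movement and HR boosts co-occur by construction.
bout_windows <- function(profile) {
  with_seed(profile$seed + 1L, {
    n <- profile$n_activity_bouts
    if (n <= 0) {
      return(data.frame(start_s = numeric(0), duration_s = numeric(0),
                        hr_boost_bpm = numeric(0), acc_g = numeric(0)))
    }
    dur <- stats::runif(n, profile$bout_duration_range_s[1],
                        profile$bout_duration_range_s[2])
    ## awake portions of the recording
    awake <- rbind(c(0, min(profile$sleep_onset_s, profile$duration_s)),
                   c(min(profile$wake_s, profile$duration_s), profile$duration_s))
    awake <- awake[awake[, 2] - awake[, 1] > 0, , drop = FALSE]
    w <- (awake[, 2] - awake[, 1])
    seg <- sample.int(nrow(awake), n, replace = TRUE, prob = w)
    start <- awake[seg, 1] + stats::runif(n) * pmax(w[seg] - dur, 0)
    data.frame(start_s = start, duration_s = dur,
               hr_boost_bpm = stats::runif(n, profile$bout_hr_boost_range_bpm[1],
                                           profile$bout_hr_boost_range_bpm[2]),
               acc_g = stats::runif(n, profile$bout_acc_range_g[1],
                                    profile$bout_acc_range_g[2]))
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Deterministic-given-seed instantaneous truth HR on the 1 s grid.
truth_hr_grid <- function(profile, bouts = bout_windows(profile)) {
  t <- seq(0, profile$duration_s - 1)
  ## smooth circadian baseline: 10-min transitions at sleep onset and wake
  asleep <- sigmoid((t - profile$sleep_onset_s) / 300) *
    sigmoid((profile$wake_s - t) / 300)
  hr <- profile$base_hr_awake_bpm +
    (profile$base_hr_sleep_bpm - profile$base_hr_awake_bpm) * asleep
  if (nrow(bouts)) {
    ## overlapping bouts combine by maximum, not sum: exertion saturates
    boost <- rep(0, length(t))
    for (i in seq_len(nrow(bouts))) {
      ## 60 s linear on/off ramps
      rel_up <- (t - bouts$start_s[i]) / 60
      rel_dn <- (bouts$start_s[i] + bouts$duration_s[i] - t) / 60
      w <- pmin(pmax(rel_up, 0), 1) * pmin(pmax(rel_dn, 0), 1)
      boost <- pmax(boost, bouts$hr_boost_bpm[i] * w)
    }
    hr <- hr + boost
  }
  if (profile$rsa_amplitude_bpm > 0) {
    hr <- hr + profile$rsa_amplitude_bpm * sin(2 * pi * t / profile$rsa_period_s)
  }
  wander <- with_seed(profile$seed + 2L,
                      ou_path(length(t), profile$hrv_wander_sd_bpm,
                              profile$hrv_wander_tau_s))
  ## pediatric physiological range
  pmin(pmax(hr + wander, 30), 210)
}

#' Generate ground-truth heart rate for one participant
#'
#' Returns both representations of the same truth: a 1 Hz [hr_series()]
#' (instantaneous HR on the grid) and an [rr_series()] of successive beats
#' whose intervals are `60000 / HR(t)` ms with small multiplicative
#' log-normal jitter.
#'
#' @param profile a [truth_profile()].
#' @return A list with elements `rr` and `hr`.
#' @export
gen_truth_hr <- function(profile) {
  stopifnot(inherits(profile, "truth_profile"))
  bouts <- bout_windows(profile)
  hr <- truth_hr_grid(profile, bouts)
  n <- length(hr)
  rr <- with_seed(profile$seed + 3L, {
    n_exp <- ceiling(profile$duration_s * max(mean(hr), 40) / 60 * 1.25) + 100
    jit <- if (profile$rr_jitter_sd > 0)
      exp(stats::rnorm(n_exp, 0, profile$rr_jitter_sd)) else rep(1, n_exp)
    bt <- numeric(n_exp); rrms <- numeric(n_exp)
    t_cur <- 0; k <- 0L
    while (TRUE) {
      h <- hr[min(floor(t_cur) + 1L, n)]
      step <- 60 / h * jit[k + 1L]
      t_cur <- t_cur + step
      if (t_cur >= profile$duration_s) break
      k <- k + 1L
      bt[k] <- t_cur; rrms[k] <- step * 1000
      if (k >= n_exp) break  # jitter pool sized generously; never in practice
    }
    rr_series(bt[seq_len(k)], rrms[seq_len(k)])
  })
  list(rr = rr,
       hr = hr_series(seq(0, profile$duration_s - 1), hr, nominal_rate_hz = 1))
}

#' Generate synthetic triaxial accelerometry for one participant
#'
#' Gravity sits on the z axis; each axis carries Gaussian noise whose SD is a
#' slowly modulated rest floor plus a bout-specific boost during the same
#' activity windows used by [gen_truth_hr()], so movement and HR boosts
#' co-occur. Counts are emitted at `scale_divisor = 512` counts per g and are
#' kept at full precision (no integer quantization).
#'
#' @param profile a [truth_profile()].
#' @return An [accel_series()].
#' @export
gen_accel <- function(profile) {
  stopifnot(inherits(profile, "truth_profile"))
  bouts <- bout_windows(profile)
  t <- seq(0, profile$duration_s - 1)
  n <- length(t)
  with_seed(profile$seed + 4L, {
    ## slow log-normal modulation of the rest floor: micro-movements vary
    ## continuously, so per-participant intensity quantiles are well defined.
    ## Awake rest carries fidget micro-movement on top of the stillness floor.
    asleep <- t >= profile$sleep_onset_s & t < profile$wake_s
    base_sd <- profile$rest_acc_noise_g +
      ifelse(asleep, 0, profile$wake_fidget_g / 2.26)
    sd_g <- base_sd * exp(ou_path(n, profile$rest_acc_modulation_sd, 300))
    if (nrow(bouts)) {
      ## 2.26 ~ E[chi_3] * sqrt(2): mean first-difference magnitude of iid
      ## axis noise with SD s is about 2.26 s, so this calibrates the bout's
      ## mean movement intensity to acc_g; overlapping bouts combine by max
      bsd <- rep(0, n)
      for (i in seq_len(nrow(bouts))) {
        idx <- t >= bouts$start_s[i] & t < bouts$start_s[i] + bouts$duration_s[i]
        bsd[idx] <- pmax(bsd[idx], bouts$acc_g[i] / 2.26)
      }
      sd_g <- sd_g + bsd
    }
    div <- 512
    accel_series(t,
                 acc_x = stats::rnorm(n, 0, sd_g) * div,
                 acc_y = stats::rnorm(n, 0, sd_g) * div,
                 acc_z = div + stats::rnorm(n, 0, sd_g) * div,
                 scale_divisor = div)
  })
}

#' Corrupt a ground-truth HR stream through a wearable error model
#'
#' Produces the wearable's nominal 1 Hz output on its own (offset) clock:
#' sample value = truth at `t - clock_offset_s` plus bias and
#' motion-dependent Gaussian noise, with dropout, fill policy, signal decay
#' and the optional sample-rate defect applied afterwards. See
#' [wearable_error_model()].
#'
#' @param truth_hr 1 Hz ground-truth [hr_series()].
#' @param accel matching [accel_series()] (or NULL for no motion coupling);
#'   must cover the same span as `truth_hr`.
#' @param model a [wearable_error_model()].
#' @param seed RNG seed for the noise and dropout draws.
#' @return An [hr_series()] at nominal 1 Hz.
#' @export
corrupt_wearable <- function(truth_hr, accel = NULL, model = wearable_error_model(),
                             seed = 1) {
  stopifnot(inherits(truth_hr, "hr_series"), inherits(model, "wearable_error_model"))
  rng <- range(truth_hr$t)
  if (!is.null(accel)) {
    if (min(accel$t) > rng[1] + 1 || max(accel$t) < rng[2] - 1)
      stop("accel does not cover the span of truth_hr")
  }
  off <- model$clock_offset_s
  t <- seq(ceiling(rng[1] + max(off, 0)), floor(rng[2] + min(off, 0)))
  base <- stats::approx(truth_hr$t, truth_hr$bpm, xout = t - off)$y

  g <- rep(0, length(t))
  if (!is.null(accel) && (model$motion_noise_coupling_bpm_per_g > 0 ||
                          model$dropout_motion_coupling_per_g > 0)) {
    mov <- accel_magnitude(accel)
    g <- nearest_value(mov$t, mov$intensity_g, t, tol = 2, default = 0)
  }
  sdv <- model$noise_sd_rest_bpm + model$motion_noise_coupling_bpm_per_g * g
  if (!is.null(model$signal_decay_start_s)) {
    sdv[t >= model$signal_decay_start_s] <-
      sdv[t >= model$signal_decay_start_s] * model$decay_noise_multiplier
  }
  with_seed(seed, {
    bpm <- base + model$bias_bpm +
      if (any(sdv > 0)) stats::rnorm(length(t), 0, sdv) else 0
    bpm <- pmin(pmax(bpm, 1), 299)  # physiological clamp of the sensor output
    p_drop <- pmin(pmax(model$dropout_prob_rest +
                          model$dropout_motion_coupling_per_g * g, 0), 1)
    dropped <- stats::runif(length(t)) < p_drop
    bpm[dropped] <- NA
    if (!is.null(model$constant_fill_bpm)) {
      bpm <- locf_fill(bpm, model$constant_fill_bpm)
    } else if (isTRUE(model$zero_fill)) {
      bpm[dropped] <- 0
    }
    if (!is.null(model$samplerate_bug)) {
      period <- max(round(1 / model$samplerate_bug$degraded_rate_hz), 1)
      keep <- t < model$samplerate_bug$start_s |
        (t - ceiling(model$samplerate_bug$start_s)) %% period == 0
      t <- t[keep]; bpm <- bpm[keep]
    }
    hr_series(t, bpm, nominal_rate_hz = 1)
  })
}

## Last-observation-carried-forward with a constant for leading NAs.
locf_fill <- function(x, lead_constant) {
  na <- is.na(x)
  if (!any(na)) return(x)
  idx <- cummax(ifelse(na, 0L, seq_along(x)))
  out <- ifelse(idx == 0L, lead_constant, x[pmax(idx, 1L)])
  out
}

## Nearest-neighbour lookup within a tolerance on sorted reference times.
nearest_value <- function(ref_t, ref_v, query_t, tol = 2, default = NA_real_) {
  if (!length(ref_t)) return(rep(default, length(query_t)))
  i <- findInterval(query_t, ref_t)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(ref_t))
  d_lo <- abs(query_t - ref_t[lo]); d_hi <- abs(query_t - ref_t[hi])
  pick <- ifelse(d_hi < d_lo, hi, lo)
  d <- pmin(d_lo, d_hi)
  out <- ref_v[pick]
  out[d > tol] <- default
  out
}
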
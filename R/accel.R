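## Movement intensity from triaxial accelerometry and per-participant
## quantile profiles used to stratify HR accuracy by activity level.

#' Movement intensity as the norm of first-differenced acceleration
#'
#' Axes are first divided by `scale_divisor` (counts per g; 512 for typical
#' raw count exports, 1 for data already in g), then differenced between
#' consecutive samples; intensity is the Euclidean norm of the difference
#' vector. First-differencing makes the measure insensitive to gravity and
#' to any constant offset, so it reflects the magnitude of *change* in
#' acceleration — i.e. bodily movement.
#'
#' @param accel an [accel_series()] with at least 2 samples.
#' @return A `data.frame` of class `movement_series` with columns `t` (the
#'   timestamps of the second sample of each pair) and `intensity_g`.
#' @export
accel_magnitude <- function(accel) {
  stopifnot(inherits(accel, "accel_series"))
  if (nrow(accel) < 2)
    stop("accel_magnitude needs at least 2 samples (first differences)")
  div <- attr(accel, "scale_divisor")
  dx <- diff(accel$acc_x / div)
  dy <- diff(accel$acc_y / div)
  dz <- diff(accel$acc_z / div)
  out <- data.frame(t = accel$t[-1], intensity_g = sqrt(dx * dx + dy * dy + dz * dz))
  class(out) <- c("movement_series", "data.frame")
  attr(out, "participant") <- attr(accel, "participant")
  out
}

#' Per-participant movement-quantile profile
#'
#' Cut points are the participant's own empirical quantile boundaries
#' (linear-interpolation quantiles, R's type-7 convention, stated for
#' reproducibility). There is no accepted set of activity-intensity
#' thresholds in g for children, and wrist- and torso-worn sensors see
#' different movements, so thresholds are individual by design. Bins are
#' half-open `[low, high)`, last bin closed.
#'
#' @param movement a [accel_magnitude()] result.
#' @param k number of quantile bins (default quartiles).
#' @return A list of class `movement_quantile_profile` with `participant`,
#'   `k`, `cut_points` (k-1 thresholds).
#' @export
quantile_profile <- function(movement, k = 4) {
  stopifnot(inherits(movement, "movement_series"), k >= 1)
  x <- movement$intensity_g
  if (length(x) < 4 * k)
    stop("need at least 4k movement samples to form a quantile profile")
  if (max(x) == min(x))
    stop(sprintf("degenerate movement distribution (all values equal) for participant %s",
                 ifelse(is.null(attr(movement, "participant")), "<unknown>",
                        attr(movement, "participant"))))
  cuts <- if (k > 1)
    stats::quantile(x, probs = seq_len(k - 1) / k, type = 7, names = FALSE)
  else numeric(0)
  structure(list(participant = attr(movement, "participant"), k = k,
                 cut_points = cuts),
            class = "movement_quantile_profile")
}

#' Assign movement-quantile labels to paired HR rows
#'
#' Movement intensity is matched to each criterion timestamp by
#' nearest-neighbour lookup within `tol_s` (both streams run near 1 Hz);
#' rows without a movement sample in range stay unlabeled (`NA`). Labels are
#' integers `1..k` via the profile's half-open bins.
#'
#' @param paired a [resample_to_criterion()] result.
#' @param movement the same participant's [accel_magnitude()] result.
#' @param profile the participant's [quantile_profile()]; participant ids
#'   must match when both are known.
#' @param tol_s nearest-neighbour tolerance in seconds.
#' @return An integer vector of labels along `paired` rows.
#' @export
assign_quantiles <- function(paired, movement, profile, tol_s = 2) {
  stopifnot(inherits(paired, "paired_series"),
            inherits(movement, "movement_series"),
            inherits(profile, "movement_quantile_profile"))
  pid <- attr(paired, "participant"); mid <- profile$participant
  if (!is.null(pid) && !is.null(mid) && pid != mid)
    stop(sprintf("quantile profile belongs to participant %s, paired series to %s",
                 mid, pid))
  g <- nearest_value(movement$t, movement$intensity_g, paired$t, tol = tol_s)
  lab <- findInterval(g, profile$cut_points) + 1L
  lab[is.na(g)] <- NA_integer_
  lab
}
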
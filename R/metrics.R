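## Clinical metrics computed from exam trajectories.  All metrics are
## recomputable from the stored trajectory tables.

#' Reflex metrics from a tendon-tap trajectory
#'
#' Baseline is the mean elbow angle over the second preceding the tap.
#' `peak_amplitude` is the maximal absolute elbow deviation from
#' baseline after the tap; `time_to_peak` its latency; `zero_crossings`
#' counts sign changes of the elbow angular velocity in the 2 s after
#' the tap (velocities below `vel_floor` are ignored, so quiescent
#' noise does not count as oscillation); `settle_time` is the last time
#' (relative to the tap) at which the elbow is outside the settle band,
#' defined as 5% of the baseline angle (floored at three standard
#' deviations of the baseline jitter).
#'
#' @param trajectory data frame with columns `time`, `elbow_angle`,
#'   `elbow_velocity` (as produced by [tendon_tap_exam()]).
#' @param tap_onset tap time (s); the trajectory must cover
#'   `[tap_onset - 1, tap_onset + 3]`.
#' @param vel_floor velocity magnitude below which sign changes are
#'   ignored (rad/s).
#' @return an object of class `reflex_metrics`: `peak_amplitude` (rad),
#'   `time_to_peak` (s), `zero_crossings`, `settle_time` (s), plus the
#'   `baseline` angle and `baseline_jitter` sd.
#' @export
compute_reflex_metrics <- function(trajectory, tap_onset,
                                   vel_floor = 1e-4) {
  t <- trajectory$time
  step <- if (length(t) > 1L) t[2] - t[1] else 0
  if (min(t) > tap_onset - 1 + step + 1e-9 ||
      max(t) < tap_onset + 3 - step - 1e-9)
    stop_invalid("trajectory must cover [tap_onset - 1, tap_onset + 3]")
  ang <- trajectory$elbow_angle
  vel <- trajectory$elbow_velocity
  pre <- t < tap_onset & t >= tap_onset - 1
  post <- t >= tap_onset
  baseline <- mean(ang[pre])
  jitter <- stats::sd(ang[pre])
  dev <- ang - baseline
  pk_idx <- which.max(abs(dev[post]))
  peak_amplitude <- abs(dev[post])[pk_idx]
  time_to_peak <- t[post][pk_idx] - tap_onset
  win2 <- t >= tap_onset & t < tap_onset + 2
  v <- vel[win2]
  v <- v[abs(v) > vel_floor]
  zero_crossings <- if (length(v) > 1L) sum(diff(sign(v)) != 0) else 0L
  band <- max(0.05 * abs(baseline), 3 * jitter)
  outside <- which(abs(dev[post]) > band)
  settle_time <- if (length(outside)) t[post][max(outside)] - tap_onset else 0
  structure(list(peak_amplitude = peak_amplitude,
                 time_to_peak = time_to_peak,
                 zero_crossings = as.integer(zero_crossings),
                 settle_time = settle_time,
                 baseline = baseline, baseline_jitter = jitter),
            class = "reflex_metrics")
}

#' @export
print.reflex_metrics <- function(x, ...) {
  cat(sprintf(paste0("<reflex_metrics> peak %.4f rad @ %.3f s, ",
                     "%d zero crossings, settles by %.2f s\n"),
              x$peak_amplitude, x$time_to_peak, x$zero_crossings,
              x$settle_time))
  invisible(x)
}

#' Reaching metrics per segment of a coordination trajectory
#'
#' For each segment of the target schedule: `endpoint_error` is the
#' hand-to-target distance at segment end; `overshoot` the maximal
#' excursion beyond the target along the approach direction (from the
#' hand position at segment start); `path_zero_crossings` counts sign
#' changes of the time derivative of the hand-target distance
#' (derivative magnitudes below `deriv_floor` m/step ignored);
#' `onset_latency` is the time to cover 10% of the commanded
#' displacement (distance from the segment's starting hand position to
#' its target); `segment_amplitude` the maximal displacement from the
#' segment's starting hand position; `monotone_fraction` the fraction
#' of non-increasing distance steps between movement onset and first
#' entry into the `epsilon` ball (1 if the segment starts inside it);
#' `post_switch_deviation` the maximal distance from a reference
#' (healthy, same-seed) hand path over the first quarter of the
#' segment.
#'
#' @param trajectory data frame with `time`, `hand_x`, `hand_y`,
#'   `hand_z`, `segment`.
#' @param targets matrix (one row per segment) of target coordinates.
#' @param epsilon "reached" radius (m).
#' @param reference optional reference trajectory (same shape and time
#'   axis) for `post_switch_deviation`; NULL yields NA for that metric.
#' @param deriv_floor floor on per-step distance changes (m).
#' @return data frame with one row per segment and the metric columns.
#' @export
compute_reach_metrics <- function(trajectory, targets, epsilon,
                                  reference = NULL, deriv_floor = 1e-5) {
  segs <- sort(unique(trajectory$segment))
  if (length(segs) != nrow(targets))
    stop_invalid("schedule segments do not tile the trajectory: ",
                 length(segs), " segments vs ", nrow(targets), " targets")
  if (!is.null(reference) && nrow(reference) != nrow(trajectory))
    stop_invalid("reference trajectory does not match the trajectory length")
  hand <- as.matrix(trajectory[, c("hand_x", "hand_y", "hand_z")])
  out <- vector("list", length(segs))
  for (si in seq_along(segs)) {
    rows <- which(trajectory$segment == segs[si])
    h <- hand[rows, , drop = FALSE]
    tgt <- targets[si, ]
    t <- trajectory$time[rows]
    d <- sqrt(rowSums(sweep(h, 2, tgt)^2))
    start <- h[1, ]
    commanded <- sqrt(sum((tgt - start)^2))
    disp <- sqrt(rowSums(sweep(h, 2, start)^2))
    segment_amplitude <- max(disp)
    endpoint_error <- d[length(d)]
    ## overshoot along the approach direction
    if (commanded > 1e-9) {
      u <- (tgt - start) / commanded
      overshoot <- max(0, max(sweep(h, 2, tgt) %*% u))
    } else overshoot <- max(0, max(disp - epsilon))
    dd <- diff(d)
    dd_sig <- dd[abs(dd) > deriv_floor]
    path_zero_crossings <- if (length(dd_sig) > 1L)
      sum(diff(sign(dd_sig)) != 0) else 0L
    onset_idx <- which(disp > 0.1 * commanded)
    onset_latency <- if (length(onset_idx)) t[onset_idx[1]] - t[1]
                     else t[length(t)] - t[1]
    inside <- which(d < epsilon)
    if (d[1] < epsilon && commanded < epsilon) {
      monotone_fraction <- 1
    } else {
      from <- if (length(onset_idx)) onset_idx[1] else 1L
      to <- if (length(inside)) max(inside[1], from + 1L) else length(d)
      win <- dd[from:(to - 1L)]
      monotone_fraction <- if (length(win)) mean(win < deriv_floor) else 1
    }
    if (!is.null(reference)) {
      quarter <- rows[seq_len(max(1L, length(rows) %/% 4L))]
      ref <- as.matrix(reference[quarter, c("hand_x", "hand_y", "hand_z")])
      post_switch_deviation <-
        max(sqrt(rowSums((hand[quarter, , drop = FALSE] - ref)^2)))
    } else post_switch_deviation <- NA_real_
    out[[si]] <- data.frame(
      segment = segs[si], endpoint_error = endpoint_error,
      overshoot = overshoot, path_zero_crossings = path_zero_crossings,
      onset_latency = onset_latency, segment_amplitude = segment_amplitude,
      monotone_fraction = monotone_fraction,
      post_switch_deviation = post_switch_deviation)
  }
  do.call(rbind, out)
}
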
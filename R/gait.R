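# Gait kinematics from a tracked centroid trajectory: path distance, maximum
# instantaneous speed, and average speed.  Positions are lightly smoothed
# before differencing because raw per-frame speeds at 100 fps are dominated
# by tracking jitter.

# centred running mean with shrinking windows at the edges
running_mean <- function(x, window) {
  if (window <= 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Gait kinematic summary
#'
#' Smooths the track with a centred moving average (window in frames, odd;
#' the window shrinks at the edges), then takes `distance` as the summed
#' Euclidean step lengths of the smoothed path, instantaneous speed as step
#' length over the inter-frame interval, `max_speed` as its maximum, and
#' `avg_speed = distance / duration`.
#'
#' @param traj a [trajectory()].
#' @param smoothing_window smoothing window in frames, odd, >= 1.  The
#'   default 5 spans 50 ms at 100 frames/s; `1` disables smoothing.
#' @return A `gait_summary` with `distance` (cm), `distance_m`, `max_speed`
#'   and `avg_speed` (cm/s), `duration` (s), and the window used.
#' @export
gait_summary <- function(traj, smoothing_window = 5) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is_scalar_num(smoothing_window) || smoothing_window < 1 ||
      smoothing_window %% 2 != 1)
    config_error("smoothing_window must be an odd count >= 1")
  n <- length(traj$t)
  if (n < 2L) data_error("trajectory must have at least 2 positions")
  xs <- running_mean(traj$x, as.integer(smoothing_window))
  ys <- running_mean(traj$y, as.integer(smoothing_window))
  steps <- sqrt(diff(xs)^2 + diff(ys)^2)
  dt <- diff(traj$t)
  speed <- steps / dt
  distance <- sum(steps)
  duration <- traj$t[n] - traj$t[1L]
  structure(list(subject_id = traj$subject_id,
                 condition_label = traj$condition_label,
                 distance = distance, distance_m = distance / 100,
                 max_speed = max(speed),
                 avg_speed = distance / duration,
                 duration = duration,
                 smoothing_window = as.integer(smoothing_window)),
            class = "gait_summary")
}

#' @export
print.gait_summary <- function(x, ...) {
  cat(sprintf(
    "<gait_summary> %s / %s: %.1f cm in %.1f s (avg %.2f, max %.2f cm/s)\n",
    x$subject_id, x$condition_label, x$distance, x$duration, x$avg_speed,
    x$max_speed))
  invisible(x)
}

#' @export
as.data.frame.gait_summary <- function(x, ...) {
  data.frame(subject_id = x$subject_id, condition_label = x$condition_label,
             distance_cm = x$distance, max_speed_cm_s = x$max_speed,
             avg_speed_cm_s = x$avg_speed, duration_s = x$duration,
             smoothing_window = x$smoothing_window, stringsAsFactors = FALSE)
}
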
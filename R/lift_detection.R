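#' Lifting-event detection parameters
#'
#' Thresholds for the rule-based detector in [detect_lifts()].  An event
#' opens when the smoothed forearm sagittal angular speed stays at or
#' above `omega_on` for at least `t_on` seconds, and closes when it stays
#' below `omega_off` for at least `t_off` seconds (hysteresis).  Events
#' shorter than `min_duration` are discarded.
#'
#' @param omega_on opening speed threshold, rad/s.
#' @param omega_off closing speed threshold, rad/s (should be
#'   `<= omega_on`).
#' @param t_on,t_off minimum sustain times for opening/closing, s.
#' @param min_duration minimum event duration, s.
#' @param smooth_window centred moving-average window, samples (odd).
#' @return A list of class `"detection_params"`.
#' @export
detection_params <- function(omega_on = 0.3, omega_off = 0.1,
                             t_on = 0.3, t_off = 0.4,
                             min_duration = 0.5, smooth_window = 5L) {
  if (omega_on < 0 || omega_off < 0 || omega_off > omega_on)
    stop_invalid("need 0 <= omega_off <= omega_on")
  if (t_on < 0 || t_off < 0 || min_duration < 0)
    stop_invalid("sustain times must be non-negative")
  structure(list(omega_on = omega_on, omega_off = omega_off,
                 t_on = t_on, t_off = t_off,
                 min_duration = min_duration,
                 smooth_window = as.integer(smooth_window)),
            class = "detection_params")
}

# centred moving average; the window shrinks symmetrically at the edges
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L || length(x) == 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect lifting events in a forearm stream
#'
#' Identifies the start and end instants of discrete lifting motions from
#' the forearm's sagittal angular speed.  The signed gyro rate is smoothed
#' with a centred moving average; its absolute value drives an open/close
#' hysteresis state machine (see [detection_params()]).  `t_start` is the
#' first sample of the qualifying supra-threshold run, `t_end` the last
#' active sample before the qualifying quiet run.
#'
#' Deterministic for fixed input and parameters; events are time-ordered
#' and non-overlapping by construction.
#'
#' @param angles an `"angle_series"` from [complementary_filter()] for the
#'   forearm (used to verify timestamp alignment; posture is sampled from
#'   it downstream).
#' @param stream the forearm [imu_stream()] the angles were fused from.
#' @param params a [detection_params()] object.
#' @return Data frame of class `"lift_events"` with columns `t_start`,
#'   `t_end`, `i_start`, `i_end` (sample indices), and `t_origin`,
#'   `i_origin` -- the last sample below `omega_off` at or before the
#'   event start, i.e. the instant just before measurable motion, where
#'   the lift-origin posture is sampled downstream.  Zero rows when
#'   nothing moves.
#' @export
detect_lifts <- function(angles, stream, params = detection_params()) {
  if (!inherits(stream, "imu_stream"))
    stop_invalid("stream must be an imu_stream")
  if (!inherits(angles, "angle_series") ||
      nrow(angles) != nrow(stream) ||
      !isTRUE(all.equal(angles$t, stream$t, tolerance = 1e-9)))
    stop_invalid("angle series and IMU stream timestamps do not match")
  n <- nrow(stream)
  dt <- stats::median(diff(stream$t))
  speed <- abs(moving_average(stream$gy, params$smooth_window))

  n_on <- max(1L, as.integer(ceiling(params$t_on / dt)))
  n_off <- max(1L, as.integer(ceiling(params$t_off / dt)))

  above <- speed >= params$omega_on
  quiet <- speed < params$omega_off
  # run_from[i]: length of the run of TRUEs starting at i
  run_from <- function(flag) {
    r <- integer(n)
    r[n] <- as.integer(flag[n])
    if (n > 1L) for (i in (n - 1L):1L) r[i] <- if (flag[i]) r[i + 1L] + 1L else 0L
    r
  }
  on_run <- run_from(above)
  off_run <- run_from(quiet)

  starts <- integer(0); ends <- integer(0)
  open <- FALSE; start <- NA_integer_; i <- 1L
  while (i <= n) {
    if (!open) {
      if (on_run[i] >= n_on) {
        start <- i; open <- TRUE; i <- i + on_run[i]
      } else i <- i + 1L
    } else {
      if (off_run[i] >= n_off) {
        starts <- c(starts, start); ends <- c(ends, i - 1L)
        open <- FALSE; i <- i + off_run[i]
      } else i <- i + 1L
    }
  }
  if (open) { starts <- c(starts, start); ends <- c(ends, n) }

  # origin: last sub-omega_off sample at or before the event start -- the
  # posture just before measurable motion, undoing the threshold +
  # smoothing delay of the opening rule
  origins <- vapply(starts, function(s) {
    j <- which(quiet[seq_len(s)])
    if (length(j)) max(j) else s
  }, integer(1))
  ev <- data.frame(t_start = stream$t[starts], t_end = stream$t[ends],
                   i_start = starts, i_end = ends,
                   t_origin = stream$t[origins], i_origin = origins)
  ev <- ev[ev$t_end - ev$t_start >= params$min_duration, , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("lift_events", "data.frame"))
}
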
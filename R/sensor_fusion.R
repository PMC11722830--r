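#' IMU sample stream for one body segment
#'
#' Wraps a data frame of timestamped tri-axial gyroscope (rad/s) and
#' accelerometer (m/s^2, gravity included) samples for one segment.
#' Columns: `t, gx, gy, gz, ax, ay, az`.  Device convention: the z axis is
#' the segment's longitudinal axis (pointing proximally, i.e. up when the
#' wearer stands), x points anteriorly, and y is the mediolateral axis
#' about which sagittal rotation occurs, so `gy` is the sagittal angular
#' rate (positive = forward tilt).
#'
#' Timestamps must be strictly increasing.  Sampling is nominally 25 Hz;
#' intervals longer than 1.5 times the nominal period are recorded in the
#' `"gaps"` attribute (sample indices preceding each gap) rather than
#' silently interpolated.
#'
#' @param samples data frame with columns `t, gx, gy, gz, ax, ay, az`.
#' @param segment one of `"forearm"`, `"upper_arm"`, `"back"`, `"thigh"`,
#'   `"calf"`.
#' @param mounting_offset fixed device-to-segment misalignment angle in the
#'   sagittal plane (rad), subtracted from accelerometer inclinations.
#' @param nominal_dt nominal sampling interval in seconds (0.04 = 25 Hz).
#' @return The data frame with class `"imu_stream"` and attributes
#'   `segment`, `mounting_offset`, `nominal_dt`, `gaps`.
#' @export
imu_stream <- function(samples, segment, mounting_offset = 0,
                       nominal_dt = 0.04) {
  need <- c("t", "gx", "gy", "gz", "ax", "ay", "az")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop_invalid("samples must be a data frame with columns ",
                 paste(need, collapse = ", "))
  segment <- match.arg(segment, SEGMENT_NAMES)
  samples <- as.data.frame(samples)[need]
  if (nrow(samples) == 0L) stop_invalid("empty IMU stream")
  if (any(!is.finite(as.matrix(samples))))
    stop_invalid("IMU samples must be finite")
  if (any(diff(samples$t) <= 0))
    stop_invalid("IMU timestamps must be strictly increasing")
  gaps <- which(diff(samples$t) > 1.5 * nominal_dt)
  structure(samples, class = c("imu_stream", "data.frame"),
            segment = segment, mounting_offset = mounting_offset,
            nominal_dt = nominal_dt, gaps = gaps)
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("IMU stream: %s, %d samples over %.2f s%s\n",
              attr(x, "segment"), nrow(x), diff(range(x$t)),
              if (length(attr(x, "gaps")))
                sprintf(" (%d gaps)", length(attr(x, "gaps"))) else ""))
  invisible(x)
}

#' Read / write the per-segment IMU CSV dialect
#'
#' One CSV per segment with a header row and columns
#' `t,gx,gy,gz,ax,ay,az` (seconds, rad/s, m/s^2).  A sidecar JSON file
#' (`<path>.json`) names the segment and its mounting-offset angle.
#'
#' @param path CSV file path.
#' @param sidecar path of the sidecar JSON; defaults to `<path>.json`.
#'   When reading, pass `segment` explicitly if no sidecar exists.
#' @param segment,mounting_offset used when no sidecar is available
#'   (reading) or written into it (writing).
#' @return `read_imu_csv()` returns an [imu_stream()];
#'   `write_imu_csv()` returns `path` invisibly.
#' @export
read_imu_csv <- function(path, sidecar = paste0(path, ".json"),
                         segment = NULL, mounting_offset = 0) {
  samples <- utils::read.csv(path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$segment)) segment <- meta$segment
    if (!is.null(meta$mounting_offset)) mounting_offset <- meta$mounting_offset
  }
  if (is.null(segment))
    stop_invalid("segment unknown: no sidecar at ", sidecar,
                 " and no segment argument")
  imu_stream(samples, segment, mounting_offset)
}

#' @rdname read_imu_csv
#' @param stream an [imu_stream()] to write.
#' @export
write_imu_csv <- function(stream, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stream, "imu_stream"))
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE)
  if (!is.null(sidecar))
    jsonlite::write_json(
      list(segment = attr(stream, "segment"),
           mounting_offset = attr(stream, "mounting_offset")),
      sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Sagittal inclination from an accelerometer reading
#'
#' Signed angle between the device's longitudinal (z) axis and the
#' measured gravity direction, projected onto the sagittal (x--z) plane:
#' `atan2(ax, az)`.  A stationary device held vertical reads
#' `(0, 0, +g)` and returns 0; tilted fully forward it reads gravity on
#' +x and returns +pi/2.
#'
#' Samples whose acceleration magnitude falls outside
#' `[accel_min, accel_max]` (free-fall-like or impact-like, where the
#' gravity direction is unreliable) return `NA`; [complementary_filter()]
#' carries the previous estimate forward over such samples.
#'
#' @param accel numeric 3-vector `(ax, ay, az)` or an n-by-3 matrix of
#'   accelerometer readings in m/s^2.
#' @param accel_min,accel_max acceptance band for the acceleration
#'   magnitude (m/s^2).
#' @return Inclination angle(s) in radians in `[-pi, pi]`, `NA` where the
#'   magnitude guard rejects the sample.
#' @examples
#' accel_inclination(c(0, 0, 9.81))          # 0
#' accel_inclination(c(9.81, 0, 0))          # pi/2
#' @export
accel_inclination <- function(accel, accel_min = 2, accel_max = 25) {
  if (is.null(dim(accel))) accel <- matrix(accel, ncol = 3, byrow = TRUE)
  if (ncol(accel) != 3L) stop_invalid("accel must have 3 components")
  mag <- sqrt(rowSums(accel^2))
  ang <- atan2(accel[, 1], accel[, 3])
  ang[!is.finite(mag) | mag < accel_min | mag > accel_max] <- NA_real_
  if (length(ang) == 1L) ang[[1]] else ang
}

#' Drift-corrected segment inclination via a complementary filter
#'
#' Fuses the integrated sagittal gyroscope rate (accurate at high
#' frequency, but drifts under bias) with the accelerometer-derived
#' inclination (noisy, but an absolute gravity reference):
#' \deqn{\theta_k = \alpha\,(\theta_{k-1} + \omega_k \Delta t_k)
#'       + (1-\alpha)\,\theta^{acc}_k}
#' initialized from the first sample's accelerometer inclination.  For a
#' static sensor with constant gyro bias `b` the steady-state error is
#' `alpha * b * dt / (1 - alpha)` -- bounded, unlike pure integration.
#'
#' Samples rejected by the acceleration-magnitude guard (see
#' [accel_inclination()]) use the gyro-only prediction for that step and
#' are flagged.  `alpha = 0` reproduces the accelerometer inclination
#' pointwise; `alpha = 1` is pure gyro integration.
#'
#' @param stream an [imu_stream()].
#' @param alpha filter coefficient in `[0, 1]`; default 0.98 at 25 Hz.
#' @param accel_min,accel_max accelerometer magnitude guard (m/s^2).
#' @return A data frame of class `"angle_series"` with columns `t`,
#'   `theta` (rad, wrapped to `[-pi, pi]`) and `flagged` (guard hits),
#'   plus a `segment` attribute; same length and timestamps as the input.
#' @export
complementary_filter <- function(stream, alpha = 0.98,
                                 accel_min = 2, accel_max = 25) {
  if (!inherits(stream, "imu_stream"))
    stop_invalid("stream must be an imu_stream")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop_invalid("alpha must be a single number in [0, 1]")
  n <- nrow(stream)
  offset <- attr(stream, "mounting_offset")
  a_inc <- accel_inclination(cbind(stream$ax, stream$ay, stream$az),
                             accel_min, accel_max) - offset
  flagged <- is.na(a_inc)
  theta <- numeric(n)
  theta[1] <- if (flagged[1]) 0 else a_inc[1]
  if (n > 1L) {
    dt <- diff(stream$t)
    gy <- stream$gy
    for (k in 2:n) {
      pred <- theta[k - 1] + gy[k] * dt[k - 1]
      theta[k] <- if (flagged[k]) pred
                  else alpha * pred + (1 - alpha) * a_inc[k]
    }
  }
  theta <- wrap_pi(theta)
  structure(data.frame(t = stream$t, theta = theta, flagged = flagged),
            class = c("angle_series", "data.frame"),
            segment = attr(stream, "segment"))
}
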
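# Independent oracles used across the suite.  These re-derive expected
# values by different routes than the implementation under test.

# Planar chain coded joint-by-joint: ankle -> knee (vertical calf) ->
# hip -> shoulder -> elbow -> hand, arm hanging downward.  Independent of
# the closed-form V/H expressions in the package.
oracle_hand_position <- function(angles, lengths) {
  ankle <- c(0, 0)
  knee <- ankle + c(0, lengths[["calf"]])
  hip <- knee + c(-lengths[["thigh"]] * sin(angles[["thigh"]]),
                  lengths[["thigh"]] * cos(angles[["thigh"]]))
  shoulder <- hip + c(lengths[["back"]] * sin(angles[["back"]]),
                      lengths[["back"]] * cos(angles[["back"]]))
  elbow <- shoulder + c(lengths[["upper_arm"]] * sin(angles[["upper_arm"]]),
                        -lengths[["upper_arm"]] * cos(angles[["upper_arm"]]))
  hand <- elbow + c(lengths[["forearm"]] * sin(angles[["forearm"]]),
                    -lengths[["forearm"]] * cos(angles[["forearm"]]))
  c(V = hand[2], H = hand[1])
}

# Brute-force event scan: naive re-statement of the hysteresis rule,
# written as plain loops over every sample.
oracle_detect <- function(speed, t, omega_on, omega_off, t_on, t_off,
                          min_duration) {
  n <- length(speed)
  dt <- stats::median(diff(t))
  n_on <- max(1, ceiling(t_on / dt))
  n_off <- max(1, ceiling(t_off / dt))
  events <- NULL
  i <- 1
  while (i <= n) {
    run <- 0
    while (i + run <= n && speed[i + run] >= omega_on) run <- run + 1
    if (run < n_on) { i <- i + 1; next }
    start <- i
    j <- i + run
    end <- NA
    while (j <= n) {
      qrun <- 0
      while (j + qrun <= n && speed[j + qrun] < omega_off) qrun <- qrun + 1
      if (qrun >= n_off) { end <- j - 1; j <- j + qrun; break }
      j <- j + qrun + 1
    }
    if (is.na(end)) { end <- n; j <- n + 1 }
    if (t[end] - t[start] >= min_duration)
      events <- rbind(events, c(start = start, end = end))
    i <- j
  }
  events
}

# default lengths used by the worked kinematics examples
example_lengths <- function() segment_lengths(0.25, 0.30, 0.50, 0.45, 0.43)

# static IMU stream at a fixed inclination with optional gyro bias
static_stream <- function(theta, duration = 60, fs = 25, bias = 0,
                          segment = "back") {
  t <- seq(0, duration, by = 1 / fs)
  imu_stream(data.frame(t = t, gx = 0, gy = bias, gz = 0,
                        ax = 9.81 * sin(theta), ay = 0,
                        az = 9.81 * cos(theta)), segment)
}

# stream following a prescribed angle track exactly (finite-difference
# gyro, gravity-projection accel), noise-free
track_stream <- function(t, theta, segment = "forearm") {
  dt <- diff(t)
  gy <- c(0, diff(theta) / dt)
  imu_stream(data.frame(t = t, gx = 0, gy = gy, gz = 0,
                        ax = 9.81 * sin(theta), ay = 0,
                        az = 9.81 * cos(theta)), segment)
}

min_jerk_blend <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}
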
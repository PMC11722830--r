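g <- 9.81

test_that("accelerometer inclination recovers known tilts", {
  expect_equal(accel_inclination(c(0, 0, g)), 0)
  expect_equal(accel_inclination(c(g, 0, 0)), pi / 2)
  expect_equal(accel_inclination(c(g * sin(pi / 6), 0, g * cos(pi / 6))),
               pi / 6)
  # backward tilt is negative
  expect_equal(accel_inclination(c(-g * sin(0.3), 0, g * cos(0.3))), -0.3)
  # magnitude guard: free-fall-like and impact-like samples are NA
  expect_true(is.na(accel_inclination(c(0.5, 0, 0.5))))
  expect_true(is.na(accel_inclination(c(30, 0, 5))))
})

test_that("static vertical sensor is a fixed point for any alpha", {
  s <- static_stream(0, duration = 5)
  for (a in c(0, 0.5, 0.98, 1)) {
    f <- complementary_filter(s, alpha = a)
    expect_equal(f$theta, rep(0, nrow(s)))
  }
})

test_that("alpha = 1 integrates a constant rate to omega * T", {
  omega <- 0.4; fs <- 25; T <- 5
  t <- seq(0, T, by = 1 / fs)
  # accel kept consistent with upright so init theta = 0; pure integration
  s <- imu_stream(data.frame(t = t, gx = 0, gy = omega, gz = 0,
                             ax = 0, ay = 0, az = g), "forearm")
  f <- complementary_filter(s, alpha = 1)
  # first sample carries no rate step
  expect_equal(tail(f$theta, 1), omega * T, tolerance = 1e-12)
})

test_that("steady-state bias error matches the closed form to 1e-6", {
  # static pose theta0 with constant gyro bias b: the filter settles at
  # theta0 + alpha * b * dt / (1 - alpha)
  dt <- 0.04
  cases <- expand.grid(theta0 = c(0, pi / 6, -0.4),
                       b = c(0.01, 0.05), alpha = c(0.9, 0.98))
  for (k in seq_len(nrow(cases))) {
    with(cases[k, ], {
      s <- static_stream(theta0, duration = 120, bias = b)
      f <- complementary_filter(s, alpha = alpha)
      analytic <- theta0 + alpha * b * dt / (1 - alpha)
      expect_equal(tail(f$theta, 1), analytic, tolerance = 1e-6)
    })
  }
})

test_that("alpha = 0 reproduces the accelerometer inclination pointwise", {
  set.seed(7)
  t <- seq(0, 4, by = 0.04)
  th <- 0.8 * sin(2 * pi * 0.5 * t)
  s <- track_stream(t, th)
  f <- complementary_filter(s, alpha = 0)
  expect_equal(f$theta, atan2(s$ax, s$az), tolerance = 1e-12)
})

test_that("output stays bounded in [-pi, pi] under wild bounded input", {
  set.seed(11)
  t <- seq(0, 30, by = 0.04)
  s <- imu_stream(data.frame(t = t,
                             gx = 0, gy = runif(length(t), -8, 8), gz = 0,
                             ax = runif(length(t), -15, 15), ay = 0,
                             az = runif(length(t), -15, 15)), "back")
  f <- complementary_filter(s, alpha = 0.99)
  expect_true(all(f$theta >= -pi & f$theta <= pi))
})

test_that("guarded samples carry the gyro-only prediction forward", {
  t <- seq(0, 1, by = 0.04)
  ax <- rep(0, length(t)); az <- rep(g, length(t))
  ax[10:12] <- 0.1; az[10:12] <- 0.1   # free-fall-like burst
  s <- imu_stream(data.frame(t = t, gx = 0, gy = 0, gz = 0,
                             ax = ax, ay = 0, az = az), "forearm")
  f <- complementary_filter(s, alpha = 0.98)
  expect_true(all(f$flagged[10:12]))
  # zero rate + carried state: angle stays put through the burst
  expect_equal(f$theta[10:12], rep(0, 3))
})

test_that("degenerate streams are rejected", {
  expect_error(imu_stream(data.frame(t = numeric(0), gx = numeric(0),
                                     gy = numeric(0), gz = numeric(0),
                                     ax = numeric(0), ay = numeric(0),
                                     az = numeric(0)), "back"), "empty")
  expect_error(imu_stream(data.frame(t = c(0, 0.04, 0.04), gx = 0, gy = 0,
                                     gz = 0, ax = 0, ay = 0, az = g),
                          "back"), "increasing")
  s <- static_stream(0, duration = 1)
  expect_error(complementary_filter(s, alpha = 1.5), "alpha")
})

test_that("sampling gaps are flagged, mounting offset is subtracted", {
  t <- c(seq(0, 1, by = 0.04), seq(1.5, 2, by = 0.04))
  s <- imu_stream(data.frame(t = t, gx = 0, gy = 0, gz = 0,
                             ax = 0, ay = 0, az = g), "thigh")
  expect_length(attr(s, "gaps"), 1L)

  s2 <- imu_stream(data.frame(t = seq(0, 2, by = 0.04), gx = 0, gy = 0,
                              gz = 0, ax = g * sin(0.2), ay = 0,
                              az = g * cos(0.2)), "thigh",
                   mounting_offset = 0.2)
  f <- complementary_filter(s2)
  expect_equal(tail(f$theta, 1), 0, tolerance = 1e-9)
})

test_that("IMU CSV round-trips through the sidecar dialect", {
  d <- withr::local_tempdir()
  s <- static_stream(0.3, duration = 2, segment = "upper_arm")
  p <- file.path(d, "ua.csv")
  write_imu_csv(s, p)
  s2 <- read_imu_csv(p)
  expect_equal(attr(s2, "segment"), "upper_arm")
  expect_equal(as.data.frame(s2), as.data.frame(s), tolerance = 1e-12)
})
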
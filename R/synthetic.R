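#' Noise profile for synthetic IMU streams
#'
#' Sensor-imperfection parameters for the trial simulator.  Per trial and
#' segment, a constant gyro bias is drawn from `N(0, gyro_bias_sd)` unless
#' `gyro_bias` fixes its magnitude (sign still random) -- the latter is
#' what the bias-sweep experiments use.  White Gaussian noise is added to
#' every gyro and accelerometer channel.  Optionally a fraction of samples
#' is masked and filled by previous-value carry-forward, emulating missing
#' motion data patched from nearby proxy information.
#'
#' Defaults are illustrative consumer-IMU magnitudes, not fitted to any
#' data set: bias sd 0.02 rad/s, gyro noise sd 0.01 rad/s, accel noise sd
#' 0.2 m/s^2, no masking.
#'
#' @param gyro_bias_sd sd of the per-segment constant gyro bias, rad/s.
#' @param gyro_bias optional fixed bias magnitude, rad/s (overrides
#'   `gyro_bias_sd`; sign random per segment).
#' @param gyro_noise_sd white gyro noise sd, rad/s.
#' @param accel_noise_sd white accelerometer noise sd, m/s^2.
#' @param missing_fraction fraction of samples masked then carried
#'   forward, in `[0, 1)`.
#' @return List of class `"noise_profile"`.
#' @export
noise_profile <- function(gyro_bias_sd = 0.02, gyro_bias = NULL,
                          gyro_noise_sd = 0.01, accel_noise_sd = 0.2,
                          missing_fraction = 0) {
  stopifnot(gyro_bias_sd >= 0, gyro_noise_sd >= 0, accel_noise_sd >= 0,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(gyro_bias_sd = gyro_bias_sd, gyro_bias = gyro_bias,
                 gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 missing_fraction = missing_fraction),
            class = "noise_profile")
}

#' @rdname noise_profile
#' @export
noise_free <- function() {
  noise_profile(gyro_bias_sd = 0, gyro_noise_sd = 0, accel_noise_sd = 0)
}

#' Generate a synthetic lifting subject
#'
#' Draws one subject's anthropometry: true segment lengths are
#' Drillis--Contini stature fractions (see [default_segment_fractions()])
#' jittered multiplicatively per segment to emulate inter-individual
#' proportion variability; "measured" lengths add tape-measurement error.
#' The ratio model sees only the measured forearm; the ratio + length
#' model sees all five measured lengths.
#'
#' Uses the current RNG state -- seed upstream for reproducibility.
#'
#' @param id subject identifier.
#' @param stature standing height in metres; by default drawn from
#'   `N(1.70, 0.09)` truncated to `[1.50, 1.95]`.
#' @param proportion_sd relative sd of the per-segment proportion jitter.
#' @param measurement_sd sd of the additive measurement error, m.
#' @param fractions stature fractions per segment.
#' @return List of class `"synthetic_subject"` with elements `id`,
#'   `stature`, `true_lengths`, `measured_lengths`, `forearm_measured`.
#' @export
synthetic_subject <- function(id, stature = NULL, proportion_sd = 0.08,
                              measurement_sd = 0.005,
                              fractions = default_segment_fractions()) {
  if (is.null(stature)) {
    repeat {
      stature <- stats::rnorm(1, 1.70, 0.09)
      if (stature >= 1.50 && stature <= 1.95) break
    }
  }
  true_len <- stature * fractions *
    (1 + stats::rnorm(length(fractions), 0, proportion_sd))
  true_len <- pmax(true_len, 0.05)
  meas <- pmax(true_len + stats::rnorm(length(true_len), 0, measurement_sd),
               0.05)
  mk <- function(x) segment_lengths(x[["forearm"]], x[["upper_arm"]],
                                    x[["back"]], x[["thigh"]], x[["calf"]])
  structure(list(id = id, stature = stature,
                 true_lengths = mk(true_len),
                 measured_lengths = mk(meas),
                 forearm_measured = meas[["forearm"]]),
            class = "synthetic_subject")
}

# shoulder position for trunk/thigh angles (ankle at origin, calf vertical)
shoulder_position <- function(theta_back, theta_thigh, lengths) {
  hip_h <- -lengths[["thigh"]] * sin(theta_thigh)
  hip_v <- lengths[["calf"]] + lengths[["thigh"]] * cos(theta_thigh)
  c(h = hip_h + lengths[["back"]] * sin(theta_back),
    v = hip_v + lengths[["back"]] * cos(theta_back))
}

# exact two-link arm inverse kinematics, elbow-down branch (relative
# elbow angle delta = theta_FA - theta_UA chosen >= 0)
arm_ik <- function(dx, dz, l_ua, l_fa) {
  r2 <- dx^2 + dz^2
  cd <- (r2 - l_ua^2 - l_fa^2) / (2 * l_ua * l_fa)
  cd <- min(1, max(-1, cd))
  delta <- acos(cd)
  psi <- atan2(dx, -dz)
  theta_ua <- psi - atan2(l_fa * sin(delta), l_ua + l_fa * cos(delta))
  c(upper_arm = theta_ua, forearm = theta_ua + delta)
}

#' Solve a whole-body posture reaching a target hand location
#'
#' Inverse of the hand-location equations, used to stage synthetic
#' trials.  Trunk and thigh angles follow a smooth stoop heuristic of the
#' target height (thigh flexion engages below knee height, trunk flexion
#' below hip height); the remaining shoulder-to-hand offset is solved by
#' exact two-link arm inverse kinematics (elbow-down branch).  When the
#' heuristic trunk angle leaves the target outside the arm's reach
#' annulus, the trunk angle is moved to the feasible value nearest the
#' heuristic on a fine grid (and, failing that, the thigh angle too), so
#' the solution is deterministic and the forward kinematics of the result
#' reproduce the target to machine precision.
#'
#' @param target numeric `c(V =, H =)` hand location, m.
#' @param lengths a [segment_lengths()] object.
#' @param trunk_max,thigh_max heuristic full-stoop angles, rad.
#' @return A [posture_angles()] object `p` with
#'   `hand_location(p, lengths)` equal to `target` to ~1e-12 m.
#' @export
solve_posture <- function(target, lengths, trunk_max = 1.1, thigh_max = 0.9) {
  stopifnot(inherits(lengths, "segment_lengths"))
  v <- unname(target[["V"]]); h <- unname(target[["H"]])
  if (!is.finite(v) || !is.finite(h))
    stop_invalid("target hand location must be finite")
  total <- sum(lengths)
  if (sqrt(v^2 + h^2) > total)
    stop_invalid(sprintf(
      "target (V=%.3f, H=%.3f) beyond full reach: distance %.3f m exceeds total chain length %.3f m",
      v, h, sqrt(v^2 + h^2), total))

  l_ua <- lengths[["upper_arm"]]; l_fa <- lengths[["forearm"]]
  r_min <- abs(l_ua - l_fa); r_max <- l_ua + l_fa
  hip_h <- lengths[["calf"]] + lengths[["thigh"]]
  knee_h <- lengths[["calf"]]

  thigh_nom <- thigh_max * max(0, (knee_h - v) / knee_h)
  trunk_nom <- trunk_max * max(0, (hip_h - v) / hip_h)

  reach_r <- function(tb, tt) {
    s <- shoulder_position(tb, tt, lengths)
    sqrt((h - s[["h"]])^2 + (v - s[["v"]])^2)
  }

  # prefer a slightly shrunk annulus (comfort margin), fall back to exact
  pick_trunk <- function(tt, lo, hi) {
    grid <- seq(-0.3, 2.2, by = 0.002)
    sh <- -lengths[["thigh"]] * sin(tt) + lengths[["back"]] * sin(grid)
    sv <- lengths[["calf"]] + lengths[["thigh"]] * cos(tt) +
      lengths[["back"]] * cos(grid)
    r <- sqrt((h - sh)^2 + (v - sv)^2)
    ok <- r >= lo & r <= hi
    if (!any(ok)) return(NULL)
    grid[ok][which.min(abs(grid[ok] - trunk_nom))]
  }

  solve_for <- function(lo, hi) {
    r0 <- reach_r(trunk_nom, thigh_nom)
    if (r0 >= lo && r0 <= hi)
      return(list(tb = trunk_nom, tt = thigh_nom))
    tb <- pick_trunk(thigh_nom, lo, hi)
    if (!is.null(tb)) return(list(tb = tb, tt = thigh_nom))
    for (tt in seq(0, 1.2, by = 0.05)) {
      tb <- pick_trunk(tt, lo, hi)
      if (!is.null(tb)) return(list(tb = tb, tt = tt))
    }
    NULL
  }

  sol <- solve_for(r_min * 1.05 + 1e-9, r_max * 0.98)
  if (is.null(sol)) sol <- solve_for(r_min, r_max)
  if (is.null(sol))
    stop_invalid(sprintf(
      paste0("target (V=%.3f, H=%.3f) unreachable: no trunk/thigh ",
             "configuration places it within the arm annulus ",
             "[%.3f, %.3f] m of the shoulder"),
      v, h, r_min, r_max))

  s <- shoulder_position(sol$tb, sol$tt, lengths)
  arm <- arm_ik(h - s[["h"]], v - s[["v"]], l_ua, l_fa)
  posture_angles(forearm = wrap_pi(arm[["forearm"]]),
                 upper_arm = wrap_pi(arm[["upper_arm"]]),
                 back = sol$tb, thigh = sol$tt)
}

# minimum-jerk position blend s(tau) on [0, 1]
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Centre of a lifting zone's (V, H) rectangle
#'
#' @param zone integer zone 1--12.
#' @param boundaries a [zone_boundaries()].
#' @return Numeric `c(V =, H =)`, metres.
#' @export
zone_centre <- function(zone, boundaries = zone_boundaries()) {
  stopifnot(length(zone) == 1L, zone %in% 1:12)
  vb <- zone_v_band(zone); hb <- zone_h_band(zone)
  ve <- boundaries$v_edges; he <- boundaries$h_edges
  # v_band 1 is the top interval
  iv <- length(ve) - vb
  c(V = (ve[iv] + ve[iv + 1]) / 2, H = (he[hb] + he[hb + 1]) / 2)
}

# jittered target inside the zone rectangle, moved toward a reachable
# anchor when the subject cannot reach it (emulating height-adjusted
# target placement); margin keeps targets off the zone edges
feasible_zone_target <- function(zone, lengths, boundaries = zone_boundaries(),
                                 jitter = 0.03, margin = 0.015) {
  vb <- zone_v_band(zone); hb <- zone_h_band(zone)
  ve <- boundaries$v_edges; he <- boundaries$h_edges
  iv <- length(ve) - vb
  rect <- c(v_lo = ve[iv] + margin, v_hi = ve[iv + 1] - margin,
            h_lo = he[hb] + margin, h_hi = he[hb + 1] - margin)
  ctr <- zone_centre(zone, boundaries)
  tgt <- c(V = ctr[["V"]] + stats::runif(1, -jitter, jitter),
           H = ctr[["H"]] + stats::runif(1, -jitter, jitter))
  tgt[["V"]] <- min(max(tgt[["V"]], rect[["v_lo"]]), rect[["v_hi"]])
  tgt[["H"]] <- min(max(tgt[["H"]], rect[["h_lo"]]), rect[["h_hi"]])

  ok <- function(p) !inherits(try(solve_posture(p, lengths), silent = TRUE),
                              "try-error")
  if (ok(tgt)) return(tgt)
  # neutral standing hand height, clamped into the rectangle, near edge
  v_neutral <- lengths[["calf"]] + lengths[["thigh"]] + lengths[["back"]] -
    lengths[["upper_arm"]] - lengths[["forearm"]]
  anchor <- c(V = min(max(v_neutral, rect[["v_lo"]]), rect[["v_hi"]]),
              H = rect[["h_lo"]])
  for (s in seq(0.05, 1, by = 0.05)) {
    p <- (1 - s) * tgt + s * anchor
    names(p) <- c("V", "H")
    if (ok(p)) return(p)
  }
  # last resort: scan the whole rectangle, nearest reachable point first
  grid <- expand.grid(V = seq(rect[["v_lo"]], rect[["v_hi"]], length.out = 9),
                      H = seq(rect[["h_lo"]], rect[["h_hi"]], length.out = 9))
  grid <- grid[order((grid$V - tgt[["V"]])^2 + (grid$H - tgt[["H"]])^2), ]
  for (k in seq_len(nrow(grid))) {
    p <- c(V = grid$V[k], H = grid$H[k])
    if (ok(p)) return(p)
  }
  stop_invalid(sprintf("no reachable target found in zone %d for this subject",
                       zone))
}

#' Simulate one symmetric lifting trial
#'
#' Stages a trial as five phases at 25 Hz: rest in neutral standing
#' (1 s), a minimum-jerk reach from neutral to the solved lift-origin
#' posture (1.5 s), a hold at the origin (1 s), a minimum-jerk lift to a
#' carry posture (1.5 s), and a final rest (1 s).  All segments share the
#' same phase clock.  Ground truth is the noise-free forward kinematics
#' of the true segment lengths at the end of the reach -- the lift
#' origin, which is also the instant the downstream pipeline scores
#' (the start of the last detected event).
#'
#' Gyro channels are the finite-difference of the segment angle plus bias
#' and white noise; accelerometer channels are gravity projected through
#' the segment angle plus white noise (linear acceleration of the segment
#' is not modelled).  Identical seeds give bit-identical output.
#'
#' @param subject a [synthetic_subject()].
#' @param zone target zone 1--12.
#' @param boundaries a [zone_boundaries()].
#' @param noise a [noise_profile()].
#' @param seed integer seed fully determining the trial.
#' @param jitter half-width of the uniform target jitter, m.
#' @param fs sampling rate, Hz.
#' @return List of class `"lift_trial"`: `streams` (list of five
#'   [imu_stream()]s), `truth` (`c(V=, H=)`), `true_zone`, `target`,
#'   `origin_angles`, `t_origin`, `seed`.
#' @export
simulate_trial <- function(subject, zone, boundaries = zone_boundaries(),
                           noise = noise_profile(), seed = 1L,
                           jitter = 0.03, fs = 25) {
  stopifnot(inherits(subject, "synthetic_subject"))
  set.seed(as.integer(seed))
  lengths <- subject$true_lengths
  target <- feasible_zone_target(zone, lengths, boundaries, jitter = jitter)
  origin <- solve_posture(target, lengths)

  # carry posture: forearm swings to horizontal unless the origin already
  # holds it high, so the lift phase always has detectable forearm motion
  carry_fa <- if (origin[["forearm"]] < 0.9) pi / 2 else 0
  carry <- c(forearm = carry_fa, upper_arm = 0, back = 0, thigh = 0)
  neutral <- c(forearm = 0, upper_arm = 0, back = 0, thigh = 0)

  dt <- 1 / fs
  dur <- c(rest1 = 1, reach = 1.5, hold = 1, lift = 1.5, rest2 = 1)
  t <- seq(0, sum(dur), by = dt)
  t_reach0 <- dur[["rest1"]]; t_origin <- t_reach0 + dur[["reach"]]
  t_lift0 <- t_origin + dur[["hold"]]; t_lift1 <- t_lift0 + dur[["lift"]]

  blend <- numeric(length(t))          # 0 = neutral..1 = origin..2 = carry
  in_reach <- t >= t_reach0 & t < t_origin
  blend[in_reach] <- min_jerk((t[in_reach] - t_reach0) / dur[["reach"]])
  blend[t >= t_origin & t < t_lift0] <- 1
  in_lift <- t >= t_lift0 & t < t_lift1
  blend[in_lift] <- 1 + min_jerk((t[in_lift] - t_lift0) / dur[["lift"]])
  blend[t >= t_lift1] <- 2

  angle_track <- function(seg) {
    th <- numeric(length(t))
    up <- blend <= 1
    th[up] <- neutral[[seg]] + blend[up] * (origin[[seg]] - neutral[[seg]])
    th[!up] <- origin[[seg]] + (blend[!up] - 1) * (carry[[seg]] - origin[[seg]])
    th
  }

  streams <- list()
  for (seg in SEGMENT_NAMES) {
    th <- if (seg == "calf") numeric(length(t)) else angle_track(seg)
    gy_true <- c(0, diff(th)) / dt
    bias <- if (!is.null(noise$gyro_bias)) {
      noise$gyro_bias * sample(c(-1, 1), 1)
    } else stats::rnorm(1, 0, noise$gyro_bias_sd)
    nsd <- noise$gyro_noise_sd; asd <- noise$accel_noise_sd
    samp <- data.frame(
      t = t,
      gx = stats::rnorm(length(t), 0, nsd),
      gy = gy_true + bias + stats::rnorm(length(t), 0, nsd),
      gz = stats::rnorm(length(t), 0, nsd),
      ax = GRAVITY * sin(th) + stats::rnorm(length(t), 0, asd),
      ay = stats::rnorm(length(t), 0, asd),
      az = GRAVITY * cos(th) + stats::rnorm(length(t), 0, asd))
    if (noise$missing_fraction > 0) {
      mask <- stats::runif(length(t)) < noise$missing_fraction
      mask[1] <- FALSE
      for (col in c("gx", "gy", "gz", "ax", "ay", "az")) {
        x <- samp[[col]]
        for (k in which(mask)) x[k] <- x[k - 1]   # carry forward
        samp[[col]] <- x
      }
    }
    streams[[seg]] <- imu_stream(samp, seg)
  }

  truth <- hand_location(origin, lengths)
  true_zone <- zone_from_vh(truth[["V"]], truth[["H"]], boundaries)$zone
  structure(list(streams = streams,
                 truth = c(V = truth[["V"]], H = truth[["H"]]),
                 true_zone = true_zone, target = target,
                 origin_angles = origin, t_origin = t_origin,
                 seed = as.integer(seed)),
            class = "lift_trial")
}

#' Simulate a full lifting experiment
#'
#' Emulates the laboratory design -- by default 10 subjects x 3
#' repetitions x 12 zones = 360 symmetric lifting trials, zone order
#' randomized per subject.  One master seed determines subjects, targets
#' and sensor noise; per-trial seeds are derived from it, so the whole
#' experiment is reproducible bit-for-bit.
#'
#' @param n_subjects,reps number of subjects and repetitions per zone.
#' @param zones integer vector of target zones.
#' @param noise a [noise_profile()].
#' @param boundaries a [zone_boundaries()].
#' @param seed master seed (integer).
#' @param ... passed to [synthetic_subject()] (e.g. `proportion_sd`).
#'
#' @details A zone-subject pair whose entire zone rectangle lies outside
#'   the subject's reach is skipped with a warning; target placement
#'   already adapts within each zone to the subject's reach, so this is
#'   rare and the default design normally keeps all 360 trials.
#' @return List of class `"lift_experiment"`: `subjects` (list),
#'   `trials` (data frame: `trial`, `subject`, `rep`, `target_zone`,
#'   `seed`, `true_v`, `true_h`, `true_zone`), `streams` (list of
#'   per-trial stream lists), `boundaries`, `noise`, `seed`.
#' @export
simulate_experiment <- function(n_subjects = 10, reps = 3, zones = 1:12,
                                noise = noise_profile(),
                                boundaries = zone_boundaries(),
                                seed = 1L, ...) {
  stopifnot(n_subjects >= 1, reps >= 1, length(zones) >= 1,
            all(zones %in% 1:12))
  seed <- as.integer(seed)
  set.seed(seed)
  subjects <- lapply(seq_len(n_subjects), function(i)
    synthetic_subject(id = i, ...))
  plan <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    z <- as.vector(replicate(reps, zones[sample.int(length(zones))]))
    data.frame(subject = i, rep = rep(seq_len(reps), each = length(zones)),
               target_zone = z)
  }))
  plan$trial <- seq_len(nrow(plan))
  plan$seed <- (seed %% 100000L) * 17000L + plan$trial

  streams <- vector("list", nrow(plan))
  plan$true_v <- plan$true_h <- NA_real_; plan$true_zone <- NA_integer_
  skipped <- logical(nrow(plan))
  for (k in seq_len(nrow(plan))) {
    tr <- tryCatch(
      simulate_trial(subjects[[plan$subject[k]]], plan$target_zone[k],
                     boundaries, noise, seed = plan$seed[k]),
      error = function(e) {
        warning(sprintf("skipping subject %d zone %d: %s",
                        plan$subject[k], plan$target_zone[k],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(tr)) { skipped[k] <- TRUE; next }
    streams[[k]] <- tr$streams
    plan$true_v[k] <- tr$truth[["V"]]
    plan$true_h[k] <- tr$truth[["H"]]
    plan$true_zone[k] <- tr$true_zone
  }
  if (any(skipped)) {
    plan <- plan[!skipped, , drop = FALSE]
    streams <- streams[!skipped]
    rownames(plan) <- NULL
  }
  structure(list(subjects = subjects,
                 trials = plan[c("trial", "subject", "rep", "target_zone",
                                 "seed", "true_v", "true_h", "true_zone")],
                 streams = streams, boundaries = boundaries, noise = noise,
                 seed = seed),
            class = "lift_experiment")
}

#' @export
print.lift_experiment <- function(x, ...) {
  cat(sprintf("Synthetic lifting experiment: %d subjects, %d trials, seed %d\n",
              length(x$subjects), nrow(x$trials), x$seed))
  invisible(x)
}
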
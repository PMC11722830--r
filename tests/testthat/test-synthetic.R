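test_that("posture solver round-trips random feasible targets to 1e-9 m", {
  set.seed(8)
  worst <- 0
  for (i in 1:60) {
    subj <- synthetic_subject(i)
    l <- subj$true_lengths
    # a feasible target by construction: forward kinematics of a
    # moderate random posture
    a <- posture_angles(runif(1, -0.3, 1.4), runif(1, -0.3, 1.0),
                        runif(1, 0, 1.2), runif(1, 0, 0.6))
    tgt <- hand_location(a, l)
    p <- solve_posture(c(V = tgt[["V"]], H = tgt[["H"]]), l)
    back <- hand_location(p, l)
    worst <- max(worst, abs(back[["V"]] - tgt[["V"]]),
                 abs(back[["H"]] - tgt[["H"]]))
  }
  expect_lt(worst, 1e-9)
})

test_that("targets beyond full reach raise an explicit infeasibility", {
  l <- example_lengths()
  expect_error(solve_posture(c(V = sum(l) + 0.1, H = 0), l), "reach")
  expect_error(solve_posture(c(V = 1.2, H = 2.5), l), "reach|annulus")
})

test_that("solved zone-centre postures land in their zone", {
  set.seed(12)
  subj <- synthetic_subject(1)
  for (z in 1:12) {
    ctr <- zone_centre(z)
    p <- try(solve_posture(ctr, subj$true_lengths), silent = TRUE)
    if (inherits(p, "try-error")) next  # centre itself may be out of reach
    hl <- hand_location(p, subj$true_lengths)
    expect_identical(zone_from_vh(hl[["V"]], hl[["H"]])$zone, z)
  }
})

test_that("feasible targets exist in every zone for extreme statures", {
  set.seed(13)
  for (st in c(1.50, 1.62, 1.80, 1.95)) {
    subj <- synthetic_subject(1, stature = st, proportion_sd = 0)
    for (z in 1:12) {
      tgt <- liftzone:::feasible_zone_target(z, subj$true_lengths)
      expect_identical(zone_from_vh(tgt[["V"]], tgt[["H"]])$zone, z)
      p <- solve_posture(tgt, subj$true_lengths)
      hl <- hand_location(p, subj$true_lengths)
      expect_lt(max(abs(hl - c(tgt[["V"]], tgt[["H"]]))), 1e-9)
    }
  }
})

test_that("identical seeds give bit-identical trials", {
  set.seed(2); subj <- synthetic_subject(1)
  t1 <- simulate_trial(subj, 9, seed = 77)
  t2 <- simulate_trial(subj, 9, seed = 77)
  expect_identical(t1, t2)
  for (seg in names(t1$streams))
    expect_identical(as.data.frame(t1$streams[[seg]]),
                     as.data.frame(t2$streams[[seg]]))
  t3 <- simulate_trial(subj, 9, seed = 78)
  expect_false(identical(t1$streams$forearm$gy, t3$streams$forearm$gy))
})

test_that("noise-free trials close the full pipeline to the true zone", {
  set.seed(6)
  subj <- synthetic_subject(3)
  for (z in c(1L, 5L, 7L, 12L)) {
    tr <- simulate_trial(subj, z, noise = noise_free(), seed = 100 + z)
    est <- estimate_trial(tr$streams, subj$true_lengths)
    expect_identical(est$pred_zone, tr$true_zone)
    expect_identical(tr$true_zone, z)
    expect_lt(abs(est$pred_v - tr$truth[["V"]]), 0.02)
    expect_lt(abs(est$pred_h - tr$truth[["H"]]), 0.02)
  }
})

test_that("trial ground truth is the forward kinematics of the origin", {
  set.seed(14)
  subj <- synthetic_subject(4)
  tr <- simulate_trial(subj, 6, noise = noise_free(), seed = 5)
  hl <- hand_location(tr$origin_angles, subj$true_lengths)
  expect_equal(unname(tr$truth), unname(c(hl[["V"]], hl[["H"]])))
})

test_that("filter bias error on a simulated trial follows the closed form", {
  # static-tail check: after the trial's final rest, a biased gyro leaves
  # the back angle near alpha*b*dt/(1-alpha) rather than b*T
  set.seed(15)
  subj <- synthetic_subject(5)
  b <- 0.05
  tr <- simulate_trial(subj, 8,
                       noise = noise_profile(gyro_bias = b,
                                             gyro_noise_sd = 0,
                                             accel_noise_sd = 0),
                       seed = 9)
  f <- complementary_filter(tr$streams$calf)  # calf stays vertical
  bias_used <- tr$streams$calf$gy[1]          # constant channel = bias
  expect_equal(abs(bias_used), b, tolerance = 1e-12)
  steady <- 0.98 * bias_used * 0.04 / 0.02
  # the trial is 6 s long; allow the remaining exponential transient
  expect_lt(abs(tail(f$theta, 1) - steady), 0.01)
})

test_that("experiment dimensions and derived labels are consistent", {
  e <- simulate_experiment(n_subjects = 2, reps = 2, zones = c(4, 5),
                           noise = noise_free(), seed = 4)
  expect_identical(nrow(e$trials), 8L)
  expect_true(all(as.character(group_from_zone(e$trials$true_zone)) == "low"))

  e1 <- simulate_experiment(n_subjects = 1, reps = 1, zones = 7,
                            noise = noise_free(), seed = 4)
  expect_identical(nrow(e1$trials), 1L)

  # true zone equals the targeted zone (targets stay inside their zone)
  e2 <- simulate_experiment(n_subjects = 2, reps = 1, zones = 1:12,
                            noise = noise_free(), seed = 10)
  expect_identical(e2$trials$true_zone, e2$trials$target_zone)
  expect_identical(nrow(e2$trials), 24L)

  # reproducibility of the whole experiment
  e3 <- simulate_experiment(n_subjects = 2, reps = 1, zones = 1:12,
                            noise = noise_free(), seed = 10)
  expect_identical(e2$trials, e3$trials)
})

test_that("masked samples are carried forward, not interpolated", {
  set.seed(16)
  subj <- synthetic_subject(6)
  tr <- simulate_trial(subj, 5,
                       noise = noise_profile(missing_fraction = 0.3),
                       seed = 3)
  # carried-forward samples create exact duplicates of the previous value
  gy <- tr$streams$forearm$gy
  expect_gt(sum(gy[-1] == gy[-length(gy)]), 10)
})

test_that("ratio-model length substitution shifts (V, H) within the
           triangle-inequality bound of the length perturbations", {
  set.seed(17)
  for (i in 1:20) {
    subj <- synthetic_subject(i)
    a <- posture_angles(runif(1, -0.5, 1.2), runif(1, -0.5, 1.0),
                        runif(1, 0, 1.4), runif(1, 0, 0.8))
    true_hl <- hand_location(a, subj$true_lengths)
    ratio_l <- segments_from_forearm(subj$forearm_measured)
    ratio_hl <- hand_location(a, ratio_l)
    dl <- abs(unclass(ratio_l) - unclass(subj$true_lengths))
    expect_lte(abs(ratio_hl[["V"]] - true_hl[["V"]]), sum(dl) + 1e-12)
    expect_lte(abs(ratio_hl[["H"]] - true_hl[["H"]]),
               sum(dl[-which(names(dl) == "calf")]) + 1e-12)
  }
})
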
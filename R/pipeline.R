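#' Estimate the hand location for one trial's IMU streams
#'
#' Runs the estimation pipeline on one trial: complementary-filter fusion
#' of each segment stream, lifting-event detection on the forearm, then
#' planar-chain forward kinematics at the scored instant.  The last
#' detected event is taken as the lift; its posture is sampled at the
#' event's origin instant (the last quiet sample before motion, see
#' [detect_lifts()]), which is where the TLV assesses the lift.  Earlier
#' events are the preparatory reach.
#'
#' @param streams named list of the five segment [imu_stream()]s.
#' @param lengths [segment_lengths()] used by the kinematic model (ratio
#'   or measured, depending on the model being evaluated).
#' @param alpha complementary-filter coefficient.
#' @param params [detection_params()].
#' @param boundaries [zone_boundaries()].
#' @return One-row data frame: `pred_v`, `pred_h`, `pred_zone`,
#'   `out_of_range`, `t_scored`, `n_events`.  Prediction columns are `NA`
#'   when no event is detected.
#' @export
estimate_trial <- function(streams, lengths, alpha = 0.98,
                           params = detection_params(),
                           boundaries = zone_boundaries()) {
  if (!all(SEGMENT_NAMES %in% names(streams)))
    stop_invalid("streams must be named with all five segments")
  angles <- lapply(streams[SEGMENT_NAMES], complementary_filter,
                   alpha = alpha)
  events <- detect_lifts(angles$forearm, streams$forearm, params)
  if (nrow(events) == 0L)
    return(data.frame(pred_v = NA_real_, pred_h = NA_real_,
                      pred_zone = NA_integer_, out_of_range = NA,
                      t_scored = NA_real_, n_events = 0L))
  i <- events$i_origin[nrow(events)]
  post <- posture_angles(forearm = angles$forearm$theta[i],
                         upper_arm = angles$upper_arm$theta[i],
                         back = angles$back$theta[i],
                         thigh = angles$thigh$theta[i])
  loc <- hand_location(post, lengths)
  z <- zone_from_vh(loc[["V"]], loc[["H"]], boundaries)
  data.frame(pred_v = loc[["V"]], pred_h = loc[["H"]],
             pred_zone = z$zone, out_of_range = z$out_of_range,
             t_scored = events$t_origin[nrow(events)],
             n_events = nrow(events))
}

model_lengths <- function(subject, model = c("ratio_length", "ratio"),
                          ratios = default_segment_ratios()) {
  model <- match.arg(model)
  if (model == "ratio") segments_from_forearm(subject$forearm_measured, ratios)
  else subject$measured_lengths
}

#' Run the estimation pipeline over a synthetic experiment
#'
#' Applies [estimate_trial()] to every trial of a [simulate_experiment()]
#' result, using either the ratio model (all segment lengths scaled from
#' the measured forearm) or the ratio + length model (individually
#' measured lengths).
#'
#' @param experiment a `"lift_experiment"`.
#' @param model `"ratio_length"` or `"ratio"`.
#' @param ratios [segment_ratios()] for the ratio model.
#' @inheritParams estimate_trial
#' @return The experiment's trial table with prediction columns appended
#'   (`model`, `pred_v`, `pred_h`, `pred_zone`, `out_of_range`,
#'   `t_scored`, `n_events`), ready for [evaluate_results()].
#' @export
estimate_hand_locations <- function(experiment,
                                    model = c("ratio_length", "ratio"),
                                    ratios = default_segment_ratios(),
                                    alpha = 0.98,
                                    params = detection_params()) {
  stopifnot(inherits(experiment, "lift_experiment"))
  model <- match.arg(model)
  res <- lapply(seq_len(nrow(experiment$trials)), function(k) {
    subj <- experiment$subjects[[experiment$trials$subject[k]]]
    estimate_trial(experiment$streams[[k]],
                   model_lengths(subj, model, ratios),
                   alpha = alpha, params = params,
                   boundaries = experiment$boundaries)
  })
  cbind(experiment$trials, model = model, do.call(rbind, res))
}

# ------------------------------------------------------------------
# command-style entry points (also driven by inst/cli/liftzone.R)

#' Simulate an experiment to disk
#'
#' Writes one IMU CSV (+ sidecar JSON) per trial and segment, a trial
#' manifest CSV with the ground truth, subject anthropometry JSONs, and a
#' YAML run manifest echoing every parameter and seed.
#'
#' @inheritParams simulate_experiment
#' @param out_dir output directory (created if absent).
#' @return The `"lift_experiment"` invisibly.
#' @export
run_simulate <- function(out_dir, n_subjects = 10, reps = 3, zones = 1:12,
                         noise = noise_profile(),
                         boundaries = zone_boundaries(), seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exp <- simulate_experiment(n_subjects, reps, zones, noise, boundaries,
                             seed, ...)
  imu_dir <- file.path(out_dir, "imu")
  dir.create(imu_dir, showWarnings = FALSE)
  for (k in seq_len(nrow(exp$trials))) {
    for (seg in SEGMENT_NAMES) {
      write_imu_csv(exp$streams[[k]][[seg]],
                    file.path(imu_dir, sprintf("trial%03d_%s.csv", k, seg)))
    }
  }
  utils::write.csv(exp$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  subj <- lapply(exp$subjects, function(s)
    list(id = s$id, stature = s$stature,
         measured_lengths = as.list(unclass(s$measured_lengths)),
         forearm_measured = s$forearm_measured))
  jsonlite::write_json(subj, file.path(out_dir, "subjects.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(list(
    n_subjects = n_subjects, reps = reps, zones = zones, seed = seed,
    noise = unclass(noise),
    boundaries = list(v_edges = boundaries$v_edges,
                      h_edges = boundaries$h_edges)),
    file.path(out_dir, "manifest.yaml"))
  invisible(exp)
}

read_experiment_meta <- function(data_dir) {
  trials <- utils::read.csv(file.path(data_dir, "trials.csv"))
  subj_raw <- jsonlite::read_json(file.path(data_dir, "subjects.json"),
                                  simplifyVector = FALSE)
  manifest <- yaml::read_yaml(file.path(data_dir, "manifest.yaml"))
  boundaries <- zone_boundaries(unlist(manifest$boundaries$v_edges),
                                unlist(manifest$boundaries$h_edges))
  subjects <- lapply(subj_raw, function(s) {
    ml <- s$measured_lengths
    structure(list(id = s$id, stature = s$stature,
                   measured_lengths = segment_lengths(
                     ml$forearm, ml$upper_arm, ml$back, ml$thigh, ml$calf),
                   forearm_measured = s$forearm_measured),
              class = "synthetic_subject")
  })
  list(trials = trials, subjects = subjects, boundaries = boundaries,
       seed = manifest$seed)
}

read_trial_streams <- function(data_dir, k) {
  out <- lapply(SEGMENT_NAMES, function(seg)
    read_imu_csv(file.path(data_dir, "imu",
                           sprintf("trial%03d_%s.csv", k, seg))))
  names(out) <- SEGMENT_NAMES
  out
}

#' Estimate hand locations for an on-disk experiment
#'
#' Reads a directory written by [run_simulate()], runs the pipeline for
#' the chosen model, and writes `results_<model>.csv`.  Trials whose IMU
#' files cannot be read are logged to stderr and emitted with `NA`
#' predictions; the run continues.
#'
#' @param data_dir directory from [run_simulate()].
#' @param model `"ratio_length"` or `"ratio"`.
#' @param out_csv output path; default inside `data_dir`.
#' @inheritParams estimate_hand_locations
#' @return The results data frame invisibly.
#' @export
run_estimate <- function(data_dir, model = c("ratio_length", "ratio"),
                         out_csv = NULL, ratios = default_segment_ratios(),
                         alpha = 0.98, params = detection_params()) {
  model <- match.arg(model)
  exp <- read_experiment_meta(data_dir)
  res <- lapply(seq_len(nrow(exp$trials)), function(k) {
    subj <- exp$subjects[[exp$trials$subject[k]]]
    tryCatch(
      estimate_trial(read_trial_streams(data_dir, k),
                     model_lengths(subj, model, ratios),
                     alpha = alpha, params = params,
                     boundaries = exp$boundaries),
      error = function(e) {
        message(sprintf("trial %d failed: %s", k, conditionMessage(e)))
        data.frame(pred_v = NA_real_, pred_h = NA_real_,
                   pred_zone = NA_integer_, out_of_range = NA,
                   t_scored = NA_real_, n_events = NA_integer_)
      })
  })
  out <- cbind(exp$trials, model = model, do.call(rbind, res))
  if (is.null(out_csv))
    out_csv <- file.path(data_dir, paste0("results_", model, ".csv"))
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}

#' Evaluate an on-disk results table
#'
#' Reads a results CSV from [run_estimate()], scores it with
#' [evaluate_results()], and writes the confusion counts, row rates and
#' metrics as CSVs plus a plain-text report.
#'
#' @param results_csv path to a results CSV.
#' @param out_dir directory for the report files (created if absent).
#' @inheritParams evaluate_results
#' @return The `"zone_evaluation"` invisibly.
#' @export
run_evaluate <- function(results_csv, out_dir = dirname(results_csv),
                         mapping = c("acgih_simplified", "los_alamos"),
                         boundaries = zone_boundaries()) {
  res <- utils::read.csv(results_csv)
  ev <- evaluate_results(res, mapping, boundaries)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sub("\\.csv$", "", basename(results_csv))
  utils::write.csv(as.data.frame(ev$counts),
                   file.path(out_dir, paste0(stem, "_confusion_counts.csv")))
  utils::write.csv(round(ev$metrics$row_rates, 4),
                   file.path(out_dir, paste0(stem, "_row_rates.csv")))
  met <- data.frame(class = RISK_LEVELS, precision = ev$metrics$precision,
                    recall = ev$metrics$recall, f = ev$metrics$f)
  utils::write.csv(met, file.path(out_dir, paste0(stem, "_metrics.csv")),
                   row.names = FALSE)
  rpt <- file.path(out_dir, paste0(stem, "_report.txt"))
  con <- file(rpt, "w"); on.exit(close(con))
  sink(con); print(ev); sink()
  invisible(ev)
}

#' Scatter plot of predicted hand locations over the zone grid
#'
#' Mirrors the published scatter-plot view: predicted (H, V) points over
#' the 12-zone grid, coloured by the trial's true zone.
#'
#' @param results results data frame with `pred_v`, `pred_h`, `true_zone`.
#' @param boundaries a [zone_boundaries()].
#' @export
plot_zone_scatter <- function(results, boundaries = zone_boundaries()) {
  ok <- !is.na(results$pred_v)
  plot(results$pred_h[ok], results$pred_v[ok],
       col = grDevices::hcl.colors(12, "Dark 3")[results$true_zone[ok]],
       pch = 19, cex = 0.6,
       xlab = "Horizontal distance H (m)", ylab = "Vertical height V (m)",
       xlim = range(boundaries$h_edges), ylim = range(boundaries$v_edges))
  graphics::abline(v = boundaries$h_edges, h = boundaries$v_edges,
                   col = "grey70")
}

#' Heat map of the per-subject zone agreement grid
#'
#' @param grid an [agreement_grid()].
#' @export
plot_agreement_heatmap <- function(grid) {
  graphics::image(x = 1:12, y = seq_len(nrow(grid)), z = t(unclass(grid)),
                  zlim = c(0, 3), col = grDevices::hcl.colors(4, "RdYlGn",
                                                              rev = TRUE),
                  xlab = "Lifting zone", ylab = "Subject",
                  main = "Trials matched per subject and zone (0-3)")
}
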
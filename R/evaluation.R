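#' Trial records for zone-accuracy evaluation
#'
#' The evaluation functions consume a data frame of trial records with (at
#' least) columns `subject`, `rep`, `true_zone`, `pred_zone` (integer
#' zones 1--12; `pred_zone` may be `NA` for trials with no detected lift
#' or missing data -- such rows are excluded from scoring and counted
#' separately).  [mean_error()] additionally needs `true_v`, `true_h`,
#' `pred_v`, `pred_h`.
#'
#' @param records data frame of trial records.
#' @name trial_records
#' @keywords internal
NULL

check_records <- function(records, need = c("true_zone", "pred_zone")) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_invalid("records must be a non-empty data frame")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_invalid("records lack column(s): ", paste(miss, collapse = ", "))
  invisible(records)
}

drop_missing_predictions <- function(records) {
  keep <- !is.na(records$pred_zone)
  structure(records[keep, , drop = FALSE], n_missing = sum(!keep))
}

# v/h band encoded in the row-major zone index
#' @rdname zone_group_map
#' @export
zone_v_band <- function(zone) (as.integer(zone) - 1L) %/% 3L + 1L

#' @rdname zone_group_map
#' @export
zone_h_band <- function(zone) (as.integer(zone) - 1L) %% 3L + 1L

#' Per-subject, per-zone agreement grid
#'
#' For each subject and true zone, counts the repetitions (0--3 in the
#' full design) whose predicted zone matched exactly -- the quantity shown
#' in the published-style clustering heat maps, where 3 means 100%
#' agreement over all three trials of that zone.
#'
#' @inheritParams trial_records
#' @return Integer matrix, subjects x 12 zones, of class
#'   `"agreement_grid"`; its total equals the exact-match count used by
#'   [zone12_accuracy()].
#' @export
agreement_grid <- function(records) {
  check_records(records, c("subject", "true_zone", "pred_zone"))
  records <- drop_missing_predictions(records)
  subjects <- sort(unique(records$subject))
  per <- table(records$subject, records$true_zone)
  if (any(per > 3L))
    stop_invalid("more than 3 repetitions for a subject-zone pair")
  hit <- records[records$pred_zone == records$true_zone, , drop = FALSE]
  grid <- matrix(0L, nrow = length(subjects), ncol = 12L,
                 dimnames = list(subject = as.character(subjects),
                                 zone = as.character(1:12)))
  if (nrow(hit)) {
    tab <- table(factor(hit$subject, levels = subjects),
                 factor(hit$true_zone, levels = 1:12))
    grid[] <- as.integer(tab)
  }
  structure(grid, class = c("agreement_grid", "matrix"))
}

#' Twelve-zone classification accuracy
#'
#' Every trial scores 0 or 100%: a predicted zone either matches the
#' motion-capture zone exactly or it does not.  The accuracy is the
#' proportion of exact matches over all scored trials.
#'
#' @inheritParams trial_records
#' @return Proportion in `[0, 1]` with attributes `n` (scored trials),
#'   `n_matched` and `n_missing` (trials without a prediction, excluded).
#'   Multiply by 100 and round for the conventional percentage report.
#' @export
zone12_accuracy <- function(records) {
  check_records(records)
  records <- drop_missing_predictions(records)
  n_missing <- attr(records, "n_missing")
  if (nrow(records) == 0L) stop_invalid("no scored trials")
  m <- sum(records$pred_zone == records$true_zone)
  structure(m / nrow(records), n = nrow(records), n_matched = m,
            n_missing = n_missing)
}

#' Grouped-risk confusion counts
#'
#' Tallies trials into a 3 x 3 matrix of true risk group (rows, from the
#' motion-capture / ground-truth zone) against predicted risk group
#' (columns).  With the full 10 x 3 x 12 design the row totals are 60
#' (low: zones 4--5), 120 (medium: zones 6--9) and 180 (high).
#'
#' @inheritParams trial_records
#' @param mapping zone-to-risk mapping, see [zone_group_map()].
#' @return 3 x 3 integer matrix with `low/medium/high` dimnames, rows =
#'   true group; attribute `n_missing`.
#' @export
confusion_counts <- function(records,
                             mapping = c("acgih_simplified", "los_alamos")) {
  check_records(records)
  records <- drop_missing_predictions(records)
  tg <- group_from_zone(records$true_zone, mapping)
  pg <- group_from_zone(records$pred_zone, mapping)
  counts <- table(true = tg, predicted = pg)
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(true = RISK_LEVELS, predicted = RISK_LEVELS))
  structure(m, n_missing = attr(records, "n_missing"))
}

#' Harmonic mean of precision and recall
#'
#' `f_score(p, r) = 2 p r / (p + r)`, defined as 0 when both are 0.
#'
#' @param p,r precision and recall in `[0, 1]` (vectorized).
#' @return F-score(s) in `[0, 1]`.
#' @examples
#' f_score(0.86, 0.51)  # 0.64
#' @export
f_score <- function(p, r) {
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Precision, recall and F-score from grouped confusion counts
#'
#' Per-class precision is computed from the raw counts
#' (`diag / column total`: the share of predictions of that class that
#' were correct), recall from the raw counts (`diag / row total`), and the
#' F-score is their harmonic mean.  Row-normalized rates (each true
#' class's row divided by its total, the published table format) are
#' reported alongside, plus unweighted macro averages and the class-size
#' weighted recall `trace / total` (the overall-accuracy view).
#'
#' Classes never predicted have undefined precision; it is reported as 0
#' and flagged in `precision_undefined`.
#'
#' @param counts 3 x 3 non-negative count matrix, rows = true group,
#'   columns = predicted group (see [confusion_counts()]).
#' @return A list of class `"confusion_summary"`: `counts`, `row_rates`,
#'   `precision`, `recall`, `f`, `macro_precision`, `macro_recall`,
#'   `macro_f`, `weighted_recall`, `precision_undefined`.
#' @export
confusion_metrics <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L)) || any(counts < 0) ||
      any(!is.finite(counts)) || any(counts != round(counts)))
    stop_invalid("counts must be a 3x3 non-negative integer matrix")
  if (is.null(dimnames(counts)))
    dimnames(counts) <- list(true = RISK_LEVELS, predicted = RISK_LEVELS)
  rs <- rowSums(counts); cs <- colSums(counts)
  row_rates <- counts / ifelse(rs == 0, NA_real_, rs)
  row_rates[is.na(row_rates)] <- 0
  undefined <- cs == 0
  precision <- ifelse(undefined, 0, diag(counts) / ifelse(cs == 0, 1, cs))
  recall <- ifelse(rs == 0, 0, diag(counts) / ifelse(rs == 0, 1, rs))
  names(precision) <- names(recall) <- RISK_LEVELS
  f <- f_score(precision, recall)
  structure(list(
    counts = counts,
    row_rates = row_rates,
    precision = precision,
    recall = recall,
    f = f,
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f = mean(f),
    weighted_recall = if (sum(counts) == 0) 0 else
      sum(diag(counts)) / sum(counts),
    precision_undefined = undefined
  ), class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, digits = 2, ...) {
  cat("Grouped lifting-risk confusion (rows = ground truth, cols = model)\n\n")
  cat("Row-normalized rates:\n")
  tab <- cbind(round(x$row_rates, digits), Sums = round(rowSums(x$row_rates), digits))
  print(tab)
  cat("\n")
  met <- rbind(`Precision p` = x$precision, `Recall r` = x$recall,
               `F-score` = x$f)
  met <- cbind(met, Avg = c(x$macro_precision, x$macro_recall, x$macro_f))
  print(round(met, digits))
  cat(sprintf("\nWeighted recall (trace/total): %.2f  [n = %d]\n",
              x$weighted_recall, sum(x$counts)))
  if (any(x$precision_undefined))
    cat("Note: precision undefined (no predictions) for:",
        paste(RISK_LEVELS[x$precision_undefined], collapse = ", "), "\n")
  invisible(x)
}

#' Per-axis band accuracy
#'
#' Proportion of scored trials whose predicted vertical band (V1--V4) and,
#' independently, horizontal band (H1--H3) match the ground truth,
#' regardless of the other axis.
#'
#' @inheritParams trial_records
#' @return Named numeric vector `c(v_accuracy =, h_accuracy =)` of
#'   proportions, with attributes `n` and `n_missing`.
#' @export
vh_band_accuracy <- function(records) {
  check_records(records)
  records <- drop_missing_predictions(records)
  if (nrow(records) == 0L) stop_invalid("no scored trials")
  v <- mean(zone_v_band(records$pred_zone) == zone_v_band(records$true_zone))
  h <- mean(zone_h_band(records$pred_zone) == zone_h_band(records$true_zone))
  structure(c(v_accuracy = v, h_accuracy = h), n = nrow(records),
            n_missing = attr(records, "n_missing"))
}

#' Mean signed hand-location errors
#'
#' Mean of (predicted - true) for V and H, overall and stratified by the
#' trial's true band, in metres (multiply by 100 for the conventional cm
#' report).
#'
#' @param records data frame with columns `true_v`, `true_h`, `pred_v`,
#'   `pred_h` (finite; rows with `NA` predictions are excluded).
#' @param boundaries a [zone_boundaries()] used to assign true bands.
#' @return List with `v_mean`, `h_mean`, `v_by_band` (V1--V4), `h_by_band`
#'   (H1--H3); empty bands are `NA`.
#' @export
mean_error <- function(records, boundaries = zone_boundaries()) {
  check_records(records, c("true_v", "true_h", "pred_v", "pred_h"))
  keep <- !is.na(records$pred_v) & !is.na(records$pred_h)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) stop_invalid("no scored trials")
  ev <- records$pred_v - records$true_v
  eh <- records$pred_h - records$true_h
  vb <- classify_v(records$true_v, boundaries)
  hb <- classify_h(records$true_h, boundaries)
  v_by <- vapply(1:4, function(b) if (any(vb == b)) mean(ev[vb == b]) else NA_real_,
                 numeric(1))
  h_by <- vapply(1:3, function(b) if (any(hb == b)) mean(eh[hb == b]) else NA_real_,
                 numeric(1))
  names(v_by) <- paste0("V", 1:4); names(h_by) <- paste0("H", 1:3)
  list(v_mean = mean(ev), h_mean = mean(eh),
       v_by_band = v_by, h_by_band = h_by)
}

#' Full evaluation report for a trial-results table
#'
#' Convenience wrapper computing the 12-zone accuracy, per-axis band
#' accuracies, agreement grid, grouped confusion counts and
#' precision/recall/F metrics, and (when V/H columns are present) mean
#' signed errors.
#'
#' @inheritParams trial_records
#' @inheritParams confusion_counts
#' @param boundaries a [zone_boundaries()] for the mean-error banding.
#' @return List of class `"zone_evaluation"` with components
#'   `zone12_accuracy`, `vh_accuracy`, `agreement`, `counts`, `metrics`,
#'   `errors` (NULL without V/H columns), `n`, `n_missing`.
#' @export
evaluate_results <- function(records,
                             mapping = c("acgih_simplified", "los_alamos"),
                             boundaries = zone_boundaries()) {
  check_records(records)
  acc <- zone12_accuracy(records)
  counts <- confusion_counts(records, mapping)
  errors <- if (all(c("true_v", "true_h", "pred_v", "pred_h") %in%
                    names(records))) mean_error(records, boundaries) else NULL
  structure(list(
    zone12_accuracy = acc,
    vh_accuracy = vh_band_accuracy(records),
    agreement = if ("subject" %in% names(records)) agreement_grid(records) else NULL,
    counts = counts,
    metrics = confusion_metrics(counts),
    errors = errors,
    n = attr(acc, "n"),
    n_missing = attr(acc, "n_missing")
  ), class = "zone_evaluation")
}

#' @export
print.zone_evaluation <- function(x, ...) {
  cat(sprintf("Trials scored: %d (missing predictions: %d)\n",
              x$n, x$n_missing))
  cat(sprintf("12-zone accuracy: %d%% (%d/%d)\n",
              round(100 * as.numeric(x$zone12_accuracy)),
              attr(x$zone12_accuracy, "n_matched"), x$n))
  cat(sprintf("V-band accuracy: %d%%, H-band accuracy: %d%%\n\n",
              round(100 * x$vh_accuracy[["v_accuracy"]]),
              round(100 * x$vh_accuracy[["h_accuracy"]])))
  print(x$metrics)
  if (!is.null(x$errors))
    cat(sprintf("\nMean V error: %.1f cm, mean H error: %.1f cm\n",
                100 * x$errors$v_mean, 100 * x$errors$h_mean))
  invisible(x)
}
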
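# deterministic full-design record set: 10 subjects x 3 reps x 12 zones,
# with predictions forced to match on a chosen set of trials
full_records <- function(n_match = 360) {
  rec <- expand.grid(subject = 1:10, rep = 1:3, true_zone = 1:12)
  rec <- rec[order(rec$subject, rec$true_zone, rec$rep), ]
  rec$pred_zone <- (rec$true_zone %% 12L) + 1L   # always wrong: next zone
  idx <- seq_len(min(n_match, nrow(rec)))
  rec$pred_zone[idx] <- rec$true_zone[idx]
  rownames(rec) <- NULL
  rec
}

test_that("twelve-zone accuracy counts exact matches only", {
  expect_equal(as.numeric(zone12_accuracy(full_records(360))), 1)
  expect_equal(round(100 * as.numeric(zone12_accuracy(full_records(15)))), 4)
  expect_equal(round(100 * as.numeric(zone12_accuracy(full_records(78)))), 22)
  expect_error(zone12_accuracy(data.frame()), "non-empty")
})

test_that("agreement grid cells count matched repetitions per zone", {
  rec <- full_records(360)
  g <- agreement_grid(rec)
  expect_true(all(g == 3L))
  expect_identical(dim(g), c(10L, 12L))

  g0 <- agreement_grid(full_records(0))
  expect_true(all(g0 == 0L))

  # grid total is the same match count zone12_accuracy uses
  rec78 <- full_records(78)
  expect_identical(sum(agreement_grid(rec78)),
                   attr(zone12_accuracy(rec78), "n_matched"))

  bad <- rbind(rec, rec[1, ])  # 4 repetitions of one subject-zone
  expect_error(agreement_grid(bad), "repetitions")
})

test_that("grouped confusion counts give 60/120/180 row totals", {
  rec <- full_records(100)
  cc <- confusion_counts(rec)
  expect_identical(unname(rowSums(cc)), c(60, 120, 180))
  # brute-force tally oracle
  tg <- as.character(group_from_zone(rec$true_zone))
  pg <- as.character(group_from_zone(rec$pred_zone))
  for (a in c("low", "medium", "high")) for (b in c("low", "medium", "high"))
    expect_identical(cc[a, b], sum(tg == a & pg == b))

  one <- data.frame(true_zone = 4, pred_zone = 12)
  c1 <- confusion_counts(one)
  expect_identical(c1["low", "high"], 1L)
  expect_identical(sum(c1), 1L)
})

test_that("precision, recall and F reproduce the worked numbers", {
  # printed worked examples: 7 correct of 31 low predictions, F of the
  # printed (p, r) pairs
  expect_equal(7 / 31, 0.2258, tolerance = 1e-4)
  expect_equal(round(f_score(0.22, 0.07), 2), 0.11)
  expect_equal(round(f_score(0.86, 0.51), 2), 0.64)
  expect_identical(f_score(0, 0), 0)

  # row totals 60/120/180 (true class sizes) and a low column of 31
  # predictions with 7 correct, as in the printed worked example
  counts <- matrix(c(7, 10, 14,   # low column
                     40, 40, 48,  # medium column
                     13, 70, 118), nrow = 3)
  m <- confusion_metrics(counts)
  expect_identical(unname(rowSums(m$counts)), c(60, 120, 180))
  expect_equal(sum(m$counts[, 1]), 31)
  expect_equal(m$precision[["low"]], 7 / 31)
  expect_equal(m$recall[["low"]], 7 / 60)
  expect_equal(m$weighted_recall, (7 + 40 + 118) / sum(counts))
})

test_that("identity-like confusion matrices score perfectly", {
  m <- confusion_metrics(diag(c(60, 120, 180)))
  expect_equal(unname(m$precision), rep(1, 3))
  expect_equal(unname(m$recall), rep(1, 3))
  expect_equal(unname(m$f), rep(1, 3))
  expect_equal(m$macro_f, 1)
  expect_equal(m$weighted_recall, 1)
  expect_true(all(abs(rowSums(m$row_rates) - 1) < 1e-9))
})

test_that("macro and weighted recall match brute-force tallies", {
  set.seed(21)
  for (i in 1:20) {
    counts <- matrix(rpois(9, 30), 3, 3)
    m <- confusion_metrics(counts)
    rs <- rowSums(counts)
    expect_equal(m$macro_recall, mean(diag(counts) / rs))
    expect_equal(m$macro_recall, mean(diag(m$row_rates)))
    expect_equal(m$weighted_recall, sum(diag(counts)) / sum(counts))
    expect_true(all(abs(rowSums(m$row_rates)[rs > 0] - 1) < 1e-9))
  }
})

test_that("never-predicted classes get zero precision and a flag", {
  counts <- matrix(c(0, 10, 0,
                     0, 30, 0,
                     0, 20, 40), 3, 3, byrow = TRUE)
  m <- confusion_metrics(counts)
  expect_identical(unname(m$precision_undefined), c(TRUE, FALSE, FALSE))
  expect_identical(m$precision[["low"]], 0)
})

test_that("per-axis band accuracies are independent of the other axis", {
  rec <- full_records(360)
  expect_equal(as.numeric(vh_band_accuracy(rec)), c(1, 1))

  # correct V band, H band always one off
  rec2 <- expand.grid(subject = 1, rep = 1:3, true_zone = 1:12)
  hb <- zone_h_band(rec2$true_zone)
  rec2$pred_zone <- rec2$true_zone + ifelse(hb < 3L, 1L, -1L)
  a <- vh_band_accuracy(rec2)
  expect_equal(a[["v_accuracy"]], 1)
  expect_equal(a[["h_accuracy"]], 0)

  # constructed mixed rates are their own oracle
  rec3 <- full_records(0)
  n <- nrow(rec3)
  vb <- zone_v_band(rec3$true_zone); hb <- zone_h_band(rec3$true_zone)
  v_ok <- seq_len(n) %in% sample(n, round(0.61 * n))
  h_ok <- seq_len(n) %in% sample(n, round(0.34 * n))
  new_vb <- ifelse(v_ok, vb, ifelse(vb < 4L, vb + 1L, vb - 1L))
  new_hb <- ifelse(h_ok, hb, ifelse(hb < 3L, hb + 1L, hb - 1L))
  rec3$pred_zone <- 3L * (new_vb - 1L) + new_hb
  a3 <- vh_band_accuracy(rec3)
  expect_equal(a3[["v_accuracy"]], mean(v_ok))
  expect_equal(a3[["h_accuracy"]], mean(h_ok))
})

test_that("mean signed errors aggregate overall and by true band", {
  set.seed(31)
  n <- 120
  rec <- data.frame(true_v = runif(n, 0.05, 1.65),
                    true_h = runif(n, 0.02, 0.70))
  rec$pred_v <- rec$true_v; rec$pred_h <- rec$true_h
  e0 <- mean_error(rec)
  expect_equal(e0$v_mean, 0); expect_equal(e0$h_mean, 0)
  expect_true(all(e0$v_by_band == 0, na.rm = TRUE))

  rec$pred_v <- rec$true_v - 0.10
  e1 <- mean_error(rec)
  expect_equal(e1$v_mean, -0.10)
  expect_true(all(abs(e1$v_by_band - (-0.10)) < 1e-12, na.rm = TRUE))

  # mixed offsets against a brute-force average
  rec$pred_v <- rec$true_v + seq(-0.2, 0.2, length.out = n)
  e2 <- mean_error(rec)
  vb <- as.integer(classify_v(rec$true_v))
  for (b in 1:4)
    expect_equal(e2$v_by_band[[b]],
                 mean((rec$pred_v - rec$true_v)[vb == b]))
})

test_that("missing predictions are excluded and reported", {
  rec <- full_records(360)
  rec$pred_zone[1:20] <- NA_integer_
  acc <- zone12_accuracy(rec)
  expect_identical(attr(acc, "n"), 340L)
  expect_identical(attr(acc, "n_missing"), 20L)
  expect_equal(as.numeric(acc), 1)
  expect_identical(sum(confusion_counts(rec)), 340L)
})
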
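test_that("precision, recall and F1 follow their definitions", {
  pr <- precision_recall_f1(8, 2, 4)
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 8 / 12)
  expect_equal(pr$f1, 2 * 0.8 * (8 / 12) / (0.8 + 8 / 12))
  expect_false(pr$degenerate)

  # P = R implies F1 = P (harmonic-mean identity)
  expect_equal(f1_measure(0.7, 0.7), 0.7)

  z <- precision_recall_f1(0, 0, 0)
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_true(z$degenerate)
  expect_true(is.nan(precision_recall_f1(0, 0, 0, na_degenerate = TRUE)$f1))

  # published worked example: P = 92.33 %, R = 91.29 % gives F1 = 91.81 %
  expect_equal(f1_measure(92.33, 91.29), 91.81, tolerance = 0.01)

  # harmonic-mean bounds
  cases <- with_seed(3, cbind(runif(50), runif(50)))
  for (i in seq_len(nrow(cases))) {
    p <- cases[i, 1]; r <- cases[i, 2]
    f <- f1_measure(p, r)
    expect_lte(f, 2 * min(p, r) + 1e-12)
    expect_lte(f, (p + r) / 2 + 1e-12)
  }
})

test_that("average precision reproduces hand-enumerated PR curves", {
  # ranked outcomes [TP, FP, TP] over 2 ground-truth boxes:
  # AP = 0.5 * 1 + 0.5 * (2/3)
  tb <- tables_for_outcomes(c(TRUE, FALSE, TRUE), 2L)
  ap <- average_precision(tb$pred, tb$gt)
  expect_equal(unname(ap), 0.5 + 0.5 * (2 / 3), tolerance = 1e-12)

  # perfect ranking
  tb2 <- tables_for_outcomes(c(TRUE, TRUE), 2L)
  expect_equal(unname(average_precision(tb2$pred, tb2$gt)), 1)

  # no correct predictions
  tb3 <- tables_for_outcomes(c(FALSE, FALSE), 2L)
  expect_equal(unname(average_precision(tb3$pred, tb3$gt)), 0)
})

test_that("AP equals exhaustive enumeration for all small rankings", {
  for (n_gt in 1:3) {
    for (n_pred in 0:6) {
      combos <- if (n_pred) expand.grid(rep(list(c(FALSE, TRUE)), n_pred))
                else data.frame()[1, , drop = FALSE]
      for (ci in seq_len(max(1L, nrow(combos)))) {
        outcomes <- if (n_pred) as.logical(combos[ci, ]) else logical(0)
        if (sum(outcomes) > n_gt) next
        tb <- tables_for_outcomes(outcomes, n_gt)
        got <- unname(average_precision(tb$pred, tb$gt))
        expect_equal(got, ap_oracle(outcomes, n_gt), tolerance = 1e-12,
                     info = paste(n_gt, paste(outcomes, collapse = "")))
      }
    }
  }
})

test_that("mAP is the arithmetic mean of the per-class APs", {
  # published per-class APs average to the published mAP
  expect_equal(mean_ap(c(91.69, 92.30, 95.90, 96.08)), 93.99,
               tolerance = 0.01)
  expect_equal(mean_ap(rep(0.42, 4)), 0.42)
  v <- with_seed(8, runif(4))
  expect_equal(mean_ap(v), mean_ap(rev(v)))
  expect_error(mean_ap(numeric()), "at least one")
})

test_that("confusion matrices count true-by-predicted pairs", {
  expect_equal(diag(confusion_matrix(c(1, 2, 3, 4), c(1, 2, 3, 4))),
               rep(1L, 4), ignore_attr = TRUE)
  m <- confusion_matrix(1L, 2L) # true licking predicted standing
  expect_equal(m["licking", "standing"], 1L, ignore_attr = TRUE)
  expect_equal(sum(m), 1L)

  truth <- with_seed(10, sample(4L, 200, TRUE))
  pred <- with_seed(11, sample(4L, 200, TRUE))
  cm <- confusion_matrix(truth, pred)
  expect_equal(unname(rowSums(cm)), as.vector(table(factor(truth, 1:4))))
  expect_equal(sum(diag(cm)), sum(truth == pred))
  expect_error(confusion_matrix(1:3, 1:2), "length")
})

test_that("time budgets conserve duration and count events by run length", {
  tb <- time_budget(rep("standing", 900), fps = 30)
  expect_equal(tb$duration_s[tb$behavior == "standing"], 30)
  expect_equal(tb$events[tb$behavior == "standing"], 1L)
  expect_equal(sum(tb$duration_s), 30)

  # alternating 30-frame licking/standing runs over 300 frames at 30 fps:
  # five 1-second licking events
  lab <- rep(rep(c("licking", "standing"), each = 30), 5)
  tb2 <- time_budget(lab, fps = 30)
  expect_equal(tb2$events[tb2$behavior == "licking"], 5L)
  expect_equal(tb2$duration_s[tb2$behavior == "licking"], 5)

  # conservation on random sequences, whole and windowed
  lab3 <- with_seed(12, sample(satsn_action_names, 480, TRUE))
  tb3 <- time_budget(lab3, fps = 16)
  expect_equal(sum(tb3$duration_s), 30)
  tbw <- time_budget(lab3, fps = 16, window_s = 10)
  for (w in unique(tbw$window))
    expect_equal(sum(tbw$duration_s[tbw$window == w]), 10)

  expect_equal(nrow(time_budget(character(), 30)), 0L)
})

test_that("full evaluation combines AP, operating point and confusion", {
  tb <- tables_for_outcomes(c(TRUE, TRUE, FALSE), 2L)
  gt <- tb$gt
  gt2 <- gt; gt2$action_id <- 2L
  gt2$x1 <- gt2$x1 + 500; gt2$x2 <- gt2$x2 + 500
  pred2 <- tb$pred[1, ]; pred2$action_id <- 2L
  pred2$x1 <- gt2$x1[1]; pred2$x2 <- gt2$x2[1]
  pred2$y1 <- gt2$y1[1]; pred2$y2 <- gt2$y2[1]
  ev <- evaluate_predictions(rbind(tb$pred, pred2), rbind(gt, gt2))
  expect_s3_class(ev, "satsn_eval")
  expect_equal(nrow(ev$per_class), 2L)
  expect_true(all(ev$per_class$ap >= 0 & ev$per_class$ap <= 1))
  expect_equal(ev$mAP, mean(ev$per_class$ap))
  # row sums of the confusion matrix equal matched ground-truth counts
  expect_lte(sum(ev$confusion), nrow(gt) + nrow(gt2))
})
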
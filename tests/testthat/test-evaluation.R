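# Confusion-matrix metrics, AUC and the array confirmation rule.

test_that("confusion metrics follow the printed closed forms", {
  perfect <- confusion_metrics(confusion_counts(10, 10, 0, 0))
  expect_equal(perfect$SEN, 1)
  expect_equal(perfect$SP, 1)
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$MCC, 1)

  r <- confusion_metrics(confusion_counts(8, 5, 3, 2))
  expect_equal(r$SEN, 8 / 10, tolerance = 1e-12)
  expect_equal(r$SP, 5 / 8, tolerance = 1e-12)
  expect_equal(r$ACC, 13 / 18, tolerance = 1e-12)
  expect_equal(r$MCC, (8 * 5 - 3 * 2) / sqrt(10 * 11 * 8 * 7), tolerance = 1e-12)
  expect_false(r$mcc_degenerate)

  expect_error(confusion_counts(0, 0, 0, 0), "all-zero")
})

test_that("metrics are count-scale invariant and MCC negates on label flip", {
  withr::with_seed(21, {
    for (i in 1:10) {
      c4 <- sample(1:50, 4)
      a <- confusion_metrics(confusion_counts(c4[1], c4[2], c4[3], c4[4]))
      b <- confusion_metrics(confusion_counts(3 * c4[1], 3 * c4[2], 3 * c4[3], 3 * c4[4]))
      expect_equal(a$SEN, b$SEN)
      expect_equal(a$SP, b$SP)
      expect_equal(a$ACC, b$ACC)
      expect_equal(a$MCC, b$MCC, tolerance = 1e-12)
      expect_gte(a$MCC, -1)
      expect_lte(a$MCC, 1)
      # flipping every prediction: TP<->FN, TN<->FP
      flip <- confusion_metrics(confusion_counts(c4[4], c4[3], c4[2], c4[1]))
      expect_equal(flip$MCC, -a$MCC, tolerance = 1e-12)
      expect_equal(flip$SEN, 1 - a$SEN, tolerance = 1e-12)
    }
  })
})

test_that("degenerate MCC denominator reports 0 with a flag", {
  r <- confusion_metrics(confusion_counts(5, 0, 0, 3))
  expect_equal(r$MCC, 0)
  expect_true(r$mcc_degenerate)
})

test_that("roc_auc matches the all-pairs count and handles ties", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c(1, 1, -1, -1)), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(1, -1), 3)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, -1, -1)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  withr::with_seed(22, {
    for (i in 1:25) {
      n <- sample(4:50, 1)
      labels <- c(1, -1, sample(c(1, -1), n - 2, replace = TRUE))
      scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
      expect_equal(roc_auc(scores, labels), brute_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("count_confusion and roc_points are consistent", {
  pred <- c(1, 1, -1, -1, 1)
  truth <- c(1, -1, -1, 1, 1)
  cc <- count_confusion(pred, truth)
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 2, TN = 1, FP = 1, FN = 1))
  pts <- roc_points(c(0.9, 0.8, 0.3, 0.2), c(1, -1, 1, -1))
  expect_equal(pts$tpr[1], 0)
  expect_equal(utils::tail(pts$tpr, 1), 1)
})

test_that("array confirmation uses >= fold semantics", {
  expect_true(array_confirmation(5000, 1000))
  expect_false(array_confirmation(4999, 1000))
  expect_error(array_confirmation(10, 0), "positive")

  # planted table mirroring the antibody-array validation structure:
  # 112 probed signals, 92 planted above the 5-fold cutoff
  withr::with_seed(23, {
    background <- 1000
    signal <- c(runif(92, 5 * background, 20 * background),
                runif(20, 0.1 * background, 4.9 * background))[sample(112)]
  })
  expect_equal(sum(array_confirmation(signal, background)), 92)
})
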
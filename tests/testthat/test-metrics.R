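# Confusion-matrix diagnostics and event matching.

test_that("statistics follow their definitions on published per-user counts", {
  # R-wave table, user 1
  cm1 <- confusion_matrix(TP = 117, FN = 6, FP = 0, TN = 32901)
  expect_equal(round_half_up(sensitivity(cm1), 4), 0.9512)
  expect_equal(specificity(cm1), 1)
  expect_equal(round_half_up(accuracy(cm1), 4), 0.9998)
  # R-wave table, user 5
  cm5 <- confusion_matrix(TP = 229, FN = 2, FP = 10, TN = 101903)
  expect_equal(round_half_up(sensitivity(cm5), 4), 0.9913)
  expect_equal(round_half_up(specificity(cm5), 4), 0.9999)
  # degenerate all-correct case
  cm <- confusion_matrix(1, 0, 0, 1)
  expect_equal(sensitivity(cm), 1)
  expect_equal(specificity(cm), 1)
  expect_equal(accuracy(cm), 1)
  expect_equal(correct_rate(cm), 100)
  expect_equal(ppv(cm), 1)
})

test_that("the tables' 'Precision' can only be overall accuracy, not PPV", {
  cm1 <- confusion_matrix(TP = 117, FN = 6, FP = 0, TN = 32901)
  expect_equal(ppv(cm1), 1)                     # 117/117, not the printed 0.9998
  expect_equal(round_half_up(accuracy(cm1), 4), 0.9998)
})

test_that("zero denominators raise errors naming the statistic", {
  expect_error(sensitivity(confusion_matrix(0, 0, 1, 1)), "sensitivity")
  expect_error(specificity(confusion_matrix(1, 1, 0, 0)), "specificity")
  expect_error(ppv(confusion_matrix(0, 1, 0, 1)), "ppv")
})

test_that("pooling sums counts, is order-invariant and associative", {
  cms <- lapply(seq_len(4), function(i)
    confusion_matrix(i, i + 1, i + 2, 10 * i))
  p <- pool(cms)
  expect_equal(p$TP, 10); expect_equal(p$FN, 14)
  expect_equal(p$FP, 18); expect_equal(p$TN, 100)
  expect_identical(pool(cms[1]), cms[[1]])
  expect_identical(pool(rev(cms)), p)
  expect_identical(pool(list(pool(cms[1:2]), pool(cms[3:4]))), p)
  expect_error(pool(list()), "empty")
  expect_equal(mean_stat(cms, sensitivity),
               mean(vapply(cms, sensitivity, numeric(1))))
})

test_that("statistics stay within [0,1] and sensitivity is monotone in TP", {
  set.seed(2)
  for (i in 1:50) {
    cm <- confusion_matrix(sample(1:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(1:500, 1))
    for (f in list(sensitivity, specificity, accuracy, ppv)) {
      v <- f(cm)
      expect_gte(v, 0); expect_lte(v, 1)
    }
    bigger <- confusion_matrix(cm$TP + 5, cm$FN, cm$FP, cm$TN)
    expect_gte(sensitivity(bigger), sensitivity(cm))
  }
})

test_that("event matching handles identity, misses and the sample-level TN count", {
  tr <- c(1, 2, 3); dt <- c(1, 2, 3)
  m <- match_events(tr, dt, 0.05, 1000)
  expect_equal(m$TP, 3); expect_equal(m$FN, 0); expect_equal(m$FP, 0)
  expect_equal(m$TN, 997)
  m2 <- match_events(1.0, 1.3, 0.1, 100)
  expect_equal(c(m2$TP, m2$FN, m2$FP, m2$TN), c(0, 1, 1, 98))
  expect_error(match_events(1:5, 1:5, 0.1, 3), "smaller")
  expect_error(match_events(c(2, 1), c(1, 2), 0.1, 10), "sorted")
})

test_that("greedy matching attains the exhaustive optimal matching cardinality", {
  set.seed(31)
  for (rep in 1:25) {
    nt <- sample(0:10, 1); nd <- sample(0:10, 1)
    truth <- sort(runif(nt, 0, 10))
    det <- sort(truth[seq_len(min(nt, nd))] + rnorm(min(nt, nd), 0, 0.2))
    if (nd > nt) det <- sort(c(det, runif(nd - nt, 0, 10)))
    m <- match_events(truth, det, 0.15, 1000)
    expect_equal(m$TP, oracle_max_matching(truth, det, 0.15))
  }
})

test_that("counts must be nonnegative integers", {
  expect_error(confusion_matrix(-1, 0, 0, 1), "nonnegative")
  expect_error(confusion_matrix(1.5, 0, 0, 1), "nonnegative")
})
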
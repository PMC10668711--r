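test_that("metrics reproduce the published field-validation table", {
  strict <- compute_metrics(confusion_counts(CP = 1509, FP = 10751,
                                             FN = 1823, CN = 1582))
  expect_equal(round_half_up(strict$accuracy, 1), 19.7)
  expect_equal(round_half_up(strict$error_pct, 1), 80.3)
  expect_equal(round_half_up(strict$sensitivity, 1), 45.3)
  expect_equal(round_half_up(strict$specificity, 1), 12.8)
  lenient <- compute_metrics(confusion_counts(CP = 3256, FP = 10751,
                                              FN = 76, CN = 1582))
  expect_equal(round_half_up(lenient$accuracy, 1), 30.9)
  expect_equal(round_half_up(lenient$error_pct, 1), 69.1)
  expect_equal(round_half_up(lenient$sensitivity, 1), 97.7)
  expect_equal(round_half_up(lenient$specificity, 1), 12.8)
})

test_that("degenerate counts yield the expected boundary values", {
  perfect <- compute_metrics(confusion_counts(CP = 7, CN = 3))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$error_pct, 0)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  # undefined ratios are NA, never zero
  no_neg <- compute_metrics(confusion_counts(FP = 0, FN = 0, CP = 5, CN = 0))
  expect_true(is.na(no_neg$specificity))
  expect_error(compute_metrics(confusion_counts()), "positive")
  expect_error(confusion_counts(CP = -1), "non-negative")
})

test_that("metric identities hold over random count vectors", {
  set.seed(123)
  for (i in 1:1000) {
    cc <- confusion_counts(CP = sample(0:5000, 1), FP = sample(0:5000, 1),
                           FN = sample(0:5000, 1), CN = sample(0:5000, 1))
    if (cc$total == 0) next
    m <- compute_metrics(cc)
    expect_equal(m$accuracy + m$error_pct, 100)
    if (cc$CP + cc$FN > 0)
      expect_equal(m$sensitivity == 100, cc$FN == 0)
  }
})

test_that("metric reports keep input order and shape", {
  fc <- field_counts()
  tab <- metrics_report(fc)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$set, c("wrong_as_FN", "wrong_as_CP"))
  expect_equal(tab$specificity, c(12.8, 12.8))
  one <- metrics_report(fc$wrong_as_FN)
  expect_equal(nrow(one), 1)
  full <- metrics_report(fc, digits = NULL)
  expect_equal(full$accuracy[1], (1509 + 1582) / 15665 * 100)
})
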
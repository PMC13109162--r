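test_that("confusion counts enumerate the 2x2 table over observation sets", {
  d <- tibble::tibble(total = c(6, 3, 1, 5), max_single = c(2, 1, 1, 2),
                      label = c("event", "event", "non_event", "non_event"))
  r5 <- list(threshold = 5L, s3 = FALSE)
  cc <- confusion_counts(d, r5)
  expect_equal(as.list(cc), list(alerts = 2L, tp = 1L, fp = 1L, tn = 1L, fn = 1L))

  all_neg <- tibble::tibble(total = c(0, 1), max_single = c(0, 1),
                            label = "non_event")
  cc2 <- confusion_counts(all_neg, r5)
  expect_equal(cc2$tn, 2L)
  expect_equal(cc2$tp + cc2$fn + cc2$fp, 0L)

  # a degenerate threshold alerts everything: no negatives remain
  cc3 <- confusion_counts(d, list(threshold = 1L, s3 = FALSE))
  expect_equal(cc3$alerts, 4L)
  expect_equal(cc3$tn, 0L)
  expect_equal(cc3$fn, 0L)

  expect_error(confusion_counts(d[0, ], r5), "empty")
  bad <- d; bad$label[1] <- "neutralized"
  expect_error(confusion_counts(bad, r5), "neutralized")
})

test_that("threshold and burden metrics satisfy their defining ratios", {
  counts <- tibble::tibble(alerts = 459L, tp = 228L, fp = 231L, tn = 4000L, fn = 300L)
  m <- threshold_metrics(counts)
  expect_equal(m$ppv, 228 / 459)
  expect_equal(m$nne, 459 / 228)
  expect_equal(m$sensitivity, 228 / 528)
  expect_equal(m$npv, 4000 / 4300)
  # undefined metrics are NA, never 0
  none <- threshold_metrics(tibble::tibble(tp = 0L, fp = 0L, tn = 5L, fn = 2L))
  expect_true(is.na(none$ppv) && is.na(none$nne))
  perfect <- threshold_metrics(tibble::tibble(tp = 10L, fp = 0L, tn = 5L, fn = 0L))
  expect_equal(perfect$nne, 1)

  b <- burden_metrics(counts, patient_days = 5154)
  expect_equal(b$roa, 100 * 459 / 5154)
  expect_equal(b$aoer, 100 * 228 / 5154)
  expect_equal(burden_metrics(tibble::tibble(alerts = 0L, tp = 0L, fp = 0L), 100)$roa, 0)
  expect_error(burden_metrics(counts, 0), "positive")
})

test_that("metric identities hold to 1e-12 on computed reports", {
  withr::with_seed(5, {
    d <- tibble::tibble(
      patient_id = rep(sprintf("p%02d", 1:20), each = 10),
      total_gews = sample(0:12, 200, replace = TRUE),
      max_single_gews = sample(0:3, 200, replace = TRUE),
      label = sample(c("event", "non_event"), 200, replace = TRUE, prob = c(.1, .9))
    )
    rep <- rule_metrics(d, trigger_rule("GEWS>=5", "gews", 5), patient_days = 180)
    expect_lt(abs(rep$nne * rep$ppv - 1), 1e-12)
    expect_lt(abs(rep$aoer - rep$ppv * rep$roa), 1e-12)
    expect_lt(abs(rep$nne - rep$roa / rep$aoer), 1e-12)
  })
})

test_that("AUROC matches worked examples, the pairwise oracle, and pROC", {
  expect_equal(auroc(c(1, 2, 3), c("non_event", "non_event", "event")), 1)
  expect_equal(auroc(c(2, 2, 2, 2), c("event", "non_event", "event", "non_event")), 0.5)
  expect_equal(auroc(c(3, 1, 2, 2), c("event", "non_event", "non_event", "event")), 0.875)
  expect_error(auroc(1:3, rep("event", 3)), "both classes")

  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      score <- sample(0:10, n, replace = TRUE)
      event <- runif(n) < 0.3
      if (!any(event) || all(event)) next
      expect_equal(auroc(score, event), oracle_auroc(score, event))
      proc <- suppressMessages(pROC::auc(pROC::roc(
        response = event, predictor = score, direction = "<", quiet = TRUE
      )))
      expect_equal(auroc(score, event), as.numeric(proc))
    }
  })
})

test_that("PR-AUC is non-interpolated average precision", {
  expect_equal(pr_auc(c(1, 2, 9, 9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  # all scores equal: precision is the prevalence at every point
  expect_identical(pr_auc(rep(3, 10), c(rep(TRUE, 3), rep(FALSE, 7))), 0.3)
  expect_equal(pr_auc(c(3, 1, 2, 2), c("event", "non_event", "non_event", "event")),
               0.5 * 1 + 0.5 * 2 / 3)
  expect_error(pr_auc(1:3, rep(FALSE, 3)), "event")

  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      score <- sample(0:8, n, replace = TRUE)
      event <- runif(n) < 0.3
      if (!any(event)) next
      expect_equal(pr_auc(score, event), oracle_ap(score, event))
    }
  })
})

test_that("raising the trigger threshold never raises sensitivity nor lowers specificity", {
  withr::with_seed(8, {
    d <- tibble::tibble(total = sample(0:12, 300, replace = TRUE),
                        max_single = sample(0:3, 300, replace = TRUE),
                        label = sample(c("event", "non_event"), 300,
                                       replace = TRUE, prob = c(.15, .85)))
    prev <- threshold_metrics(confusion_counts(d, list(threshold = 1L, s3 = FALSE)))
    for (th in 2:12) {
      cur <- threshold_metrics(confusion_counts(d, list(threshold = th, s3 = FALSE)))
      expect_lte(cur$sensitivity, prev$sensitivity)
      expect_gte(cur$specificity, prev$specificity)
      prev <- cur
    }
  })
})

test_that("sample-size arithmetic and ward rescaling are exact products", {
  expect_equal(expected_event_count(500, 10, 0.005), 25)
  expect_equal(expected_event_count(0, 10, 0.005), 0)
  expect_equal(expected_event_count(541, 10, 0.0077), 41.657)
  # a fully occupied 24-bed ward accrues 24 patient-days per 24 h
  expect_equal(ward_rate(100, beds = 24, hours = 24), 24)
  expect_equal(ward_rate(8.906), 8.906 * 0.24)
  tr <- burden_tradeoff(1.463, 0.102)
  expect_equal(tr$alarms_per_event, 1.463 / 0.102)
  expect_equal(tr$false_alarms_per_event, 1.463 / 0.102 - 1)
})
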
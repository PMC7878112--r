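test_that("micro one-vs-rest pooling matches brute-force enumeration", {
  y_true <- c(0, 0, 1, 1, 2, 2)
  y_pred <- c(0, 1, 1, 1, 2, 0)
  oracle <- ovr_counts_bruteforce(y_true, y_pred)
  counts <- micro_ovr_counts(confusion_matrix(y_true, y_pred))
  expect_equal(c(TP = counts$TP, FP = counts$FP, FN = counts$FN,
                 TN = counts$TN), oracle)
  expect_equal(unname(oracle), c(4, 2, 2, 10))
  rep <- metric_battery(counts)
  expect_equal(rep$value[rep$metric == "recall"], 2 / 3)
  expect_equal(rep$value[rep$metric == "false_positive_rate"], 1 / 6)

  # property: pooled formulas agree with enumeration on random label vectors
  withr::with_seed(21, {
    for (i in 1:20) {
      k <- sample(2:8, 1)
      n <- sample(10:60, 1)
      yt <- sample(k, n, replace = TRUE)
      yp <- sample(k, n, replace = TRUE)
      oc <- ovr_counts_bruteforce(yt, yp)
      mc <- micro_ovr_counts(confusion_matrix(yt, yp, levels = 1:k))
      expect_equal(c(mc$TP, mc$FP, mc$FN, mc$TN), unname(oc))
    }
  })
})

test_that("perfect and worst-case classifiers hit the analytic corners", {
  perfect <- diag(8) * 25
  c8 <- micro_ovr_counts(perfect)
  rep <- metric_battery(c8)
  val <- function(m) rep$value[rep$metric == m]
  expect_equal(val("prevalence"), 0.125)
  expect_equal(val("recall"), 1)
  expect_equal(val("false_positive_rate"), 0)
  expect_equal(val("accuracy"), 1)
  expect_equal(val("matthews_correlation"), 1)
  expect_identical(val("positive_likelihood_ratio"), Inf)
  expect_identical(val("diagnostic_odds_ratio"), Inf)

  all_wrong <- matrix(c(0, 5, 5, 0), 2)
  rep2 <- metric_battery(micro_ovr_counts(all_wrong))
  expect_equal(rep2$value[rep2$metric == "recall"], 0)
  expect_equal(rep2$value[rep2$metric == "false_positive_rate"], 1)
})

test_that("battery identities hold for random valid counts", {
  withr::with_seed(31, {
    for (i in 1:30) {
      cts <- binary_counts(TP = runif(1, 1, 50), FP = runif(1, 1, 50),
                           FN = runif(1, 1, 50), TN = runif(1, 1, 50))
      r <- metric_battery(cts)
      v <- function(m) r$value[r$metric == m]
      expect_equal(v("positive_likelihood_ratio"),
                   v("recall") / v("false_positive_rate"), tolerance = 1e-12)
      expect_equal(v("negative_likelihood_ratio"),
                   v("false_negative_rate") / v("true_negative_rate"),
                   tolerance = 1e-12)
      expect_equal(v("diagnostic_odds_ratio"),
                   v("positive_likelihood_ratio") /
                     v("negative_likelihood_ratio"), tolerance = 1e-12)
      expect_equal(v("informedness"),
                   v("recall") + v("true_negative_rate") - 1,
                   tolerance = 1e-12)
      expect_equal(v("markedness"),
                   v("precision") + v("negative_predictive_value") - 1,
                   tolerance = 1e-12)
      expect_equal(v("f_score"),
                   2 * v("precision") * v("recall") /
                     (v("precision") + v("recall")), tolerance = 1e-12)
      expect_equal(v("g_measure"), sqrt(v("precision") * v("recall")),
                   tolerance = 1e-12)
      rates <- r$value[r$metric %in% c(
        "accuracy", "precision", "false_discovery_rate",
        "false_omission_rate", "negative_predictive_value", "prevalence",
        "recall", "false_positive_rate", "false_negative_rate",
        "true_negative_rate", "f_score", "g_measure"
      )]
      expect_true(all(rates >= 0 & rates <= 1))
    }
  })
})

test_that("pooled OvR forces markedness = informedness = MCC", {
  withr::with_seed(41, {
    for (i in 1:10) {
      k <- sample(3:8, 1)
      cm <- matrix(rpois(k * k, 5), k, k)
      r <- metric_battery(micro_ovr_counts(cm))
      v <- function(m) r$value[r$metric == m]
      expect_equal(v("informedness"), v("markedness"), tolerance = 1e-12)
      expect_equal(v("informedness"), v("matthews_correlation"),
                   tolerance = 1e-12)
      expect_equal(v("precision"), v("recall"), tolerance = 1e-12)
      expect_equal(v("prevalence"), 1 / k, tolerance = 1e-12)
      expect_equal(v("false_omission_rate"), v("false_positive_rate"),
                   tolerance = 1e-12)
    }
  })
})

test_that("counts from a printed micro-precision regenerate the battery", {
  r <- metric_battery(counts_from_accuracy(0.80335, k = 8))
  v <- function(m) r$value[r$metric == m]
  expect_equal(v("precision"), 0.80335)
  expect_equal(v("recall"), 0.80335)
  expect_equal(v("prevalence"), 0.125)
  expect_equal(v("false_positive_rate"), (1 - 0.80335) / 7)
  expect_equal(v("f_score"), 0.80335)
  expect_equal(v("g_measure"), 0.80335)
  expect_error(counts_from_accuracy(1.2, 8))
})

test_that("degenerate confusion inputs are rejected", {
  expect_error(micro_ovr_counts(matrix(0, 3, 3)), "empty")
  expect_error(micro_ovr_counts(matrix(1, 2, 3)), "square")
  expect_error(micro_ovr_counts(matrix(-1, 2, 2)), "non-negative")
  expect_error(binary_counts(-1, 0, 0, 2), "non-negative")
})
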
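# independent oracle: metrics computed by a different route (vector
# arithmetic + Pearson correlation for the MCC)
oracleMetrics <- function(truth, pred) {
  tp <- sum(pred[truth == 1] == 1); fn <- sum(pred[truth == 1] == 0)
  tn <- sum(pred[truth == 0] == 0); fp <- sum(pred[truth == 0] == 1)
  mcc <- suppressWarnings(cor(truth, pred))
  c(accuracy = mean(truth == pred),
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    mcc = if (is.na(mcc)) 0 else mcc)
}

test_that("confusion counts match hand enumeration", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(cc[c("tp", "fn", "tn", "fp")],
                   list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  truth <- rbinom(50, 1, 0.5)
  cc <- confusionCounts(truth, truth)
  expect_identical(cc$tp + cc$tn, 50L)
  empty <- confusionCounts(integer(0), integer(0))
  expect_identical(unlist(empty), c(tp = 0L, fp = 0L, tn = 0L, fn = 0L, n = 0L))
  expect_error(confusionCounts(c(1, 0), c(1)), "length mismatch")
  expect_error(confusionCounts(c(1, 2), c(1, 0)), "0 or 1")
})

test_that("the metric suite agrees with an independent oracle on random inputs", {
  set.seed(42)
  for (rep in 1:220) {
    n <- sample(4:200, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, runif(1, 0.1, 0.9))
    got <- metricSuite(confusionCounts(truth, pred))
    want <- oracleMetrics(truth, pred)
    expect_equal(as.numeric(got), as.numeric(want[names(got)]),
                 tolerance = 1e-12)
  }
  # worked closed-form example
  m <- metricSuite(list(tp = 40, fn = 10, tn = 30, fp = 20))
  expect_equal(unname(m["accuracy"]), 0.70)
  expect_equal(unname(m["precision"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(m["sensitivity"]), 0.80)
  expect_equal(unname(m["specificity"]), 0.60)
  expect_equal(unname(m["mcc"]),
               (40 * 30 - 20 * 10) / sqrt(60 * 50 * 50 * 40), tolerance = 1e-12)
})

test_that("perfect and inverted classifiers hit the MCC extremes exactly", {
  truth <- rep(c(0, 1), 100)
  perfect <- metricSuite(confusionCounts(truth, truth))
  expect_identical(unname(perfect[c("accuracy", "precision", "sensitivity",
                                    "specificity")]), rep(1, 4))
  expect_identical(unname(perfect["mcc"]), 1)
  inverted <- metricSuite(confusionCounts(truth, 1 - truth))
  expect_identical(unname(inverted["mcc"]), -1)
  # MCC sign flips exactly under prediction complement on balanced inputs
  set.seed(7)
  pred <- rbinom(200, 1, 0.5)
  a <- metricSuite(confusionCounts(truth, pred))[["mcc"]]
  b <- metricSuite(confusionCounts(truth, 1 - pred))[["mcc"]]
  expect_equal(a, -b, tolerance = 1e-12)
})

test_that("zero-denominator metrics report 0 with an explicit flag", {
  m <- metricSuite(list(tp = 0, fp = 0, tn = 10, fn = 5))
  expect_identical(unname(m["precision"]), 0)
  expect_true("precision" %in% attr(m, "undefined"))
  expect_error(metricSuite(list(tp = 0, fp = 0, tn = 0, fn = 0)), "zero")
})

test_that("ROC curves are valid staircases with the expected landmarks", {
  truth <- c(1, 1, 0, 0)
  perfect <- rocCurve(truth, c(0.9, 0.8, 0.2, 0.1))
  expect_identical(perfect[1, ], data.frame(fpr = 0, tpr = 0))
  expect_identical(unlist(perfect[nrow(perfect), ]), c(fpr = 1, tpr = 1))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  expect_true(all(diff(perfect$fpr) >= 0) && all(diff(perfect$tpr) >= 0))

  flat <- rocCurve(truth, rep(0.5, 4))
  expect_identical(nrow(flat), 2L)  # single grouped threshold: diagonal
  expect_equal(aucTrapezoid(flat), 0.5)

  reversed <- rocCurve(truth, c(0.1, 0.2, 0.8, 0.9))
  expect_true(any(reversed$fpr == 1 & reversed$tpr == 0))
  expect_error(rocCurve(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("AUC behaves like the trapezoidal area it is", {
  truth <- c(1, 1, 0, 0)
  expect_equal(aucTrapezoid(rocCurve(truth, c(0.9, 0.8, 0.2, 0.1))), 1.0)
  expect_equal(aucTrapezoid(rocCurve(truth, c(0.1, 0.2, 0.8, 0.9))), 0.0)

  set.seed(11)
  truth <- rbinom(10000, 1, 0.5)
  scores <- runif(10000)
  aucRandom <- aucTrapezoid(rocCurve(truth, scores))
  expect_lt(abs(aucRandom - 0.5), 0.02)

  # invariance under strictly monotone score transforms
  base <- aucTrapezoid(rocCurve(truth, scores))
  expect_equal(aucTrapezoid(rocCurve(truth, qlogis(scores * 0.98 + 0.01))), base)
  expect_equal(aucTrapezoid(rocCurve(truth, scores^3)), base)

  # cross-check against an established implementation
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(base, ref, tolerance = 1e-10)
})

test_that("the operating point of a thresholded classifier lies on its own ROC", {
  set.seed(13)
  truth <- rbinom(400, 1, 0.5)
  scores <- plogis(rnorm(400) + truth)
  curve <- rocCurve(truth, scores)
  pred <- as.integer(scores > 0.5)
  m <- metricSuite(confusionCounts(truth, pred))
  pt <- c(1 - m[["specificity"]], m[["sensitivity"]])
  hit <- any(abs(curve$fpr - pt[1]) < 1e-12 & abs(curve$tpr - pt[2]) < 1e-12)
  expect_true(hit)
})

test_that("repeat aggregation reports mean and sample sd per metric", {
  rep1 <- c(accuracy = 0.5, mcc = 0.1)
  rep2 <- c(accuracy = 0.7, mcc = 0.3)
  agg <- aggregateRepeats(list(rep1, rep2))
  expect_equal(unname(agg$mean["accuracy"]), 0.6)
  expect_equal(unname(agg$sd["accuracy"]), sd(c(0.5, 0.7)))
  same <- aggregateRepeats(rep(list(rep1), 20))
  expect_equal(unname(same$mean), unname(rep1))
  expect_identical(unname(same$sd), c(0, 0))
  expect_identical(same$repeats, 20L)
  expect_error(aggregateRepeats(list()), "no reports")
  # mean lies within the input range for every metric
  reports <- lapply(1:5, function(i) c(accuracy = runif(1), mcc = runif(1, -1, 1)))
  agg <- aggregateRepeats(reports)
  vals <- do.call(rbind, reports)
  expect_true(all(agg$mean >= apply(vals, 2, min) & agg$mean <= apply(vals, 2, max)))
})
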
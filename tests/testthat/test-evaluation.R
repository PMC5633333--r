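test_that("AUC matches exhaustive pair counting, ties included", {
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(aucScore(runif(4), rep(1, 4)), "both classes")
  set.seed(41)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    probs <- round(runif(n), sample(1:3, 1)) # coarse rounding forces ties
    expect_equal(aucScore(probs, labels), naiveAuc(probs, labels))
    # trapezoidal area under the sens/spec curve agrees with the rank form
    cv <- rocCurve(probs, labels)
    fpr <- 1 - cv$specificity
    area <- sum(diff(fpr) * (head(cv$sensitivity, -1) +
                               tail(cv$sensitivity, -1)) / 2)
    expect_equal(area, aucScore(probs, labels), tolerance = 1e-10)
    # complement identity needs tie-free scores
    pt <- runif(n)
    expect_equal(aucScore(pt, labels) + aucScore(pt, 1 - labels), 1)
    # invariance under a strictly monotone transform
    expect_equal(aucScore(qlogis(pt), labels), aucScore(pt, labels))
  }
})

test_that("AUC90 matches grid integration and its analytic anchors", {
  # perfect separation
  expect_equal(auc90(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # exactly diagonal empirical ROC: every score tied between classes
  s <- rep(1:20, 2)
  y <- rep(c(1, 0), each = 20)
  expect_equal(aucScore(s, y), 0.5)
  expect_equal(auc90(s, y), 0.05)
  set.seed(42)
  for (i in 1:15) {
    n <- sample(10:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    probs <- round(runif(n), sample(1:3, 1))
    expect_lt(abs(auc90(probs, labels) - naiveAuc90(probs, labels, n = 2e6)),
              1e-6)
  }
  expect_true(auc90(runif(50), sample(0:1, 50, TRUE)) <= 1)
})

test_that("AUC and AUC90 agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  y <- sample(0:1, 300, TRUE)
  p <- runif(300) + 0.4 * y
  r <- pROC::roc(y, p, quiet = TRUE)
  expect_equal(aucScore(p, y), as.numeric(pROC::auc(r)), tolerance = 1e-10)
  pauc <- as.numeric(pROC::auc(r, partial.auc = c(0.9, 1),
                               partial.auc.focus = "specificity"))
  expect_equal(auc90(p, y), pauc / 0.1, tolerance = 1e-10)
})

test_that("correlated-AUC test is antisymmetric and matches DeLong", {
  set.seed(44)
  y <- sample(0:1, 200, TRUE)
  a <- runif(200) + 0.5 * y
  b <- 0.6 * a + 0.4 * runif(200)
  same <- compareAucCorrelated(a, a, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- compareAucCorrelated(a, b, y)
  ba <- compareAucCorrelated(b, a, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  skip_if_not_installed("pROC")
  rt <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                       pROC::roc(y, b, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(ab$z, unname(rt$statistic), tolerance = 1e-8)
  expect_equal(ab$p, rt$p.value, tolerance = 1e-8)
})

test_that("event metrics implement the overlap rules", {
  ann <- data.frame(onset = 0, offset = 60)
  hit <- eventMetrics(data.frame(onset = 30, offset = 90), ann, 1)
  expect_equal(hit$gdr, 1)
  expect_equal(hit$fdPerHour, 0)
  miss <- eventMetrics(data.frame(onset = 120, offset = 180), ann, 1)
  expect_equal(miss$gdr, 0)
  expect_equal(miss$fdPerHour, 1)
  dbl <- eventMetrics(data.frame(onset = c(5, 40), offset = c(20, 55)),
                      ann, 1)
  expect_equal(dbl$gdr, 1)
  expect_equal(dbl$nDetected, 1)
  expect_equal(dbl$fdPerHour, 0)
})

test_that("relative improvement is the normalised headroom gain", {
  expect_equal(relativeImprovement(0.9, 0.8), 0.5)
  expect_equal(relativeImprovement(0.7, 0.7), 0)
  expect_equal(relativeImprovement(0.7, 0.8), -0.5)
  expect_error(relativeImprovement(0.9, 1), "< 1")
})

test_that("the fixed false-detection budget picks a valid operating point", {
  co <- generateCohort(tinyCohortConfig(seed = 71, nPatients = 2, hours = 1))
  # perfectly informative series: probabilities equal to the labels
  seriesList <- lapply(co, function(r) {
    ProbabilitySeries(clampProbs(epochLabels(r)), "FUSION")
  })
  op <- gdrAtFdBudget(seriesList, co, fdBudget = 0.2)
  expect_equal(op$gdr, 1)
  expect_equal(op$fdPerHour, 0)
  # a seizure-free record with repeated false spikes above every candidate
  # threshold can never meet the budget
  quiet <- generateCohort(tinyCohortConfig(seed = 72, nPatients = 1,
                                           hours = 1,
                                           seizureRatePerHour = 0))[[1]]
  v <- rep(0.01, nEpochs(quiet))
  spikes <- seq(1, nEpochs(quiet) - 1, by = 40)
  v[spikes] <- 0.9; v[spikes + 1] <- 0.9
  op2 <- gdrAtFdBudget(list(ProbabilitySeries(v, "FUSION")), list(quiet),
                       fdBudget = 0.2, thresholds = seq(0.05, 0.5, 0.05))
  expect_true(is.na(op2$threshold))
})
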
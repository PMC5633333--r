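test_that("occupational likelihood matches direct density ratios", {
  g1 <- ClassGMM(matrix(0), 1, matrix(1), "NS")
  expect_equal(as.numeric(occupationalLikelihood(0.3, g1)), 1)

  # identical components: responsibilities equal the weights for any x
  g2 <- ClassGMM(matrix(c(1, 1)), c(0.3, 0.7), matrix(c(2, 2)), "NS")
  expect_equal(as.numeric(occupationalLikelihood(-4, g2)), c(0.3, 0.7))

  g3 <- ClassGMM(matrix(c(0, 1)), c(0.5, 0.5), matrix(c(1, 1)), "NS")
  r <- as.numeric(occupationalLikelihood(0, g3))
  expect_equal(r, c(dnorm(0), dnorm(1)) / (dnorm(0) + dnorm(1)),
               tolerance = 1e-12)
  expect_equal(round(r, 4), c(0.6225, 0.3775))

  set.seed(21)
  for (i in 1:10) {
    g <- randomGMMInstance()
    X <- matrix(rnorm(5 * ncol(gmmMeans(g)), sd = 2), 5)
    resp <- occupationalLikelihood(X, g)
    expect_true(all(resp >= 0 & resp <= 1))
    expect_equal(rowSums(resp), rep(1, 5), tolerance = 1e-10)
    naive <- do.call(rbind, lapply(seq_len(nrow(X)), function(i) {
      naiveOccupancy(X[i, ], gmmMeans(g), gmmWeights(g), gmmVariances(g))
    }))
    expect_equal(resp, naive, tolerance = 1e-10)
  }
})

test_that("weighted data means reduce to plain means and match the oracle", {
  g1 <- ClassGMM(matrix(c(0, 0), 1), 1, matrix(c(1, 1), 1), "NS")
  set.seed(22)
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(weightedDataMean(X, g1, 1), colMeans(X))
  g2 <- randomGMMInstance(D = 2, M = 2)
  x1 <- rnorm(2)
  expect_equal(weightedDataMean(matrix(x1, 1), g2, 1), x1)
  expect_equal(weightedDataMean(matrix(x1, 1), g2, 2), x1)
  st <- naiveStats(X, gmmMeans(g2), gmmWeights(g2), gmmVariances(g2))
  for (m in 1:2) {
    expect_equal(weightedDataMean(X, g2, m), st$E[m, ] / st$mass[m],
                 tolerance = 1e-12)
  }
  expect_error(weightedDataMean(X[0, , drop = FALSE], g2, 1), "empty")
})

test_that("conventional MAP update obeys its closed forms and oracle", {
  set.seed(23)
  g <- randomGMMInstance(D = 2, M = 3)
  X <- matrix(rnorm(40, sd = 2), 20, 2)
  # alpha = 1: no movement, any number of iterations
  expect_identical(gmmMeans(conventionalMapUpdate(g, X, 1, nIter = 5)),
                   gmmMeans(g))
  # alpha = 0, single component: jumps to the sample mean and stays
  g1 <- ClassGMM(matrix(c(5, -5), 1), 1, matrix(c(1, 1), 1), "NS")
  a0 <- conventionalMapUpdate(g1, X, 0, nIter = 3)
  expect_equal(as.numeric(gmmMeans(a0)), colMeans(X))
  # 3-iteration trajectory matches the step-by-step naive recomputation
  for (i in 1:5) {
    g <- randomGMMInstance()
    X <- matrix(rnorm(15 * ncol(gmmMeans(g)), sd = 2), 15)
    upd <- conventionalMapUpdate(g, X, 0.5, nIter = 3)
    naive <- naiveConventionalMap(gmmMeans(g), gmmWeights(g),
                                  gmmVariances(g), X, 0.5, nIter = 3)
    expect_equal(gmmMeans(upd), naive, tolerance = 1e-10)
  }
  expect_warning(conventionalMapUpdate(g, X[0, , drop = FALSE], 0.5),
                 "unchanged")
})

test_that("probability-space partition tiles [0,1]", {
  p1 <- partitionProbabilitySpace(1)
  expect_equal(p1@lower, 0)
  expect_equal(p1@upper, 1)
  p5 <- partitionProbabilitySpace(5)
  expect_equal(p5@lower, seq(0, 0.8, 0.2))
  expect_equal(p5@upper, seq(0.2, 1, 0.2))
  expect_error(partitionProbabilitySpace(0), "K")
  # every probability on a grid belongs to exactly one bin
  for (p in seq(0, 1, 0.1)) {
    inBin <- (p >= p5@lower & p < p5@upper) | (p == 1 & p5@upper == 1)
    expect_equal(sum(inBin), 1)
  }
})

test_that("cluster assignment follows the direct and complementary rules", {
  part <- partitionProbabilitySpace(10)
  a <- assignClusters(0.95, part)
  expect_equal(a$IS[[10]], 1L)
  expect_equal(a$INS[[1]], 1L)
  # 0.5 falls in the same bin for both classes
  b <- assignClusters(rep(0.5, 4), part)
  expect_equal(b$IS[[6]], 1:4)
  expect_equal(b$INS[[6]], 1:4)
  # random series: each class's sets partition all indices (brute force)
  set.seed(24)
  p <- runif(100)
  cl <- assignClusters(p, part)
  for (side in c("IS", "INS")) {
    all100 <- sort(unlist(cl[[side]]))
    expect_identical(all100, 1:100)
  }
  # membership agrees with the direct floor-rule oracle
  for (k in 1:10) {
    expect_identical(cl$IS[[k]], which(naiveBin(p, 10) == k))
    expect_identical(cl$INS[[k]], which(naiveBin(1 - p, 10) == k))
  }
})

test_that("weight schedules normalise to a partition of unity", {
  for (kind in c("linear", "sigmoid", "exp1", "exp2")) {
    for (K in c(5, 10, 25)) {
      s <- sampleWeightSchedule(kind, K)
      expect_lt(abs(scheduleAlpha(s) + sum(scheduleBeta(s)) - 1), 1e-12)
      expect_gt(scheduleAlpha(s), max(scheduleBeta(s)))
      expect_true(all(diff(s@h) >= -1e-12))
    }
  }
  # linear, K = 2: h = (0.25, 0.75); default hbar = 1 -> beta = h/2
  s2 <- sampleWeightSchedule("linear", 2)
  expect_equal(s2@h, c(0.25, 0.75))
  expect_equal(scheduleBeta(s2), c(0.125, 0.375))
  expect_equal(scheduleAlpha(s2), 0.5)
  # the main experimental configuration exists and validates
  expect_s4_class(sampleWeightSchedule("exp2", 10), "WeightSchedule")
  expect_error(sampleWeightSchedule("nope", 5), "one of")
  # K = 1 with default hbar: alpha would tie with beta_1 -> rejected
  expect_error(sampleWeightSchedule("linear", 1), "alpha")
})

test_that("confidence-weighted update collapses to conventional MAP at K=1", {
  set.seed(25)
  for (i in 1:10) {
    gS <- randomGMMInstance(tag = "S")
    D <- ncol(gmmMeans(gS))
    gNS <- randomGMMInstance(D = D, tag = "NS")
    X <- matrix(rnorm(12 * D, sd = 2), 12, D)
    p <- runif(12)
    sched <- sampleWeightSchedule("exp2", 1, hbar = 3)
    part <- partitionProbabilitySpace(1)
    upd <- confidenceWeightedMapUpdate(gS, gNS, X, p, sched, part)
    expect_equal(gmmMeans(upd$gmmS),
                 gmmMeans(conventionalMapUpdate(gS, X, scheduleAlpha(sched))))
    expect_equal(gmmMeans(upd$gmmNS),
                 gmmMeans(conventionalMapUpdate(gNS, X, scheduleAlpha(sched))))
  }
})

test_that("alpha = 1 limit leaves both models bit-identical", {
  set.seed(26)
  gS <- randomGMMInstance(tag = "S")
  gNS <- randomGMMInstance(D = ncol(gmmMeans(gS)), tag = "NS")
  X <- matrix(rnorm(30 * ncol(gmmMeans(gS))), 30)
  sched <- sampleWeightSchedule("exp2", 10, hbar = Inf)
  expect_equal(scheduleAlpha(sched), 1)
  upd <- confidenceWeightedMapUpdate(gS, gNS, X, runif(30), sched,
                                     partitionProbabilitySpace(10),
                                     nIter = 3)
  expect_identical(gmmMeans(upd$gmmS), gmmMeans(gS))
  expect_identical(gmmMeans(upd$gmmNS), gmmMeans(gNS))
})

test_that("confidence-weighted update matches the literal triple-loop oracle", {
  set.seed(27)
  for (i in 1:10) {
    K <- sample(c(1, 2, 5), 1)
    gS <- randomGMMInstance(tag = "S")
    D <- ncol(gmmMeans(gS))
    gNS <- randomGMMInstance(D = D, tag = "NS")
    N <- sample(5:20, 1)
    X <- matrix(rnorm(N * D, sd = 2), N, D)
    p <- runif(N)
    sched <- if (K == 1) {
      sampleWeightSchedule("sigmoid", 1, hbar = 1)
    } else {
      sampleWeightSchedule("sigmoid", K)
    }
    part <- partitionProbabilitySpace(K)
    upd <- confidenceWeightedMapUpdate(gS, gNS, X, p, sched, part)
    oS <- naiveConfidenceMap(gmmMeans(gS), gmmWeights(gS), gmmVariances(gS),
                             X, naiveBin(p, K), scheduleAlpha(sched),
                             scheduleBeta(sched), K)
    oNS <- naiveConfidenceMap(gmmMeans(gNS), gmmWeights(gNS),
                              gmmVariances(gNS), X, naiveBin(1 - p, K),
                              scheduleAlpha(sched), scheduleBeta(sched), K)
    expect_equal(gmmMeans(upd$gmmS), oS, tolerance = 1e-10)
    expect_equal(gmmMeans(upd$gmmNS), oNS, tolerance = 1e-10)
  }
})

test_that("adaptation with one point per component at the means is idempotent", {
  # X drawn exactly at the current means, K = 1, M = 1: the occupancy-
  # weighted data mean equals the current mean, so the update is a fixed
  # point; alpha = 0 (pure data) shows it most sharply
  g <- ClassGMM(matrix(c(1.5, -2), 1), 1, matrix(c(1, 1), 1), "S")
  X <- gmmMeans(g)
  expect_equal(gmmMeans(conventionalMapUpdate(g, X, 0, nIter = 3)),
               gmmMeans(g), tolerance = 1e-12)
  sched <- sampleWeightSchedule("linear", 1, hbar = 2)
  upd <- confidenceWeightedMapUpdate(g, g, X, 0.9, sched,
                                     partitionProbabilitySpace(1))
  expect_equal(gmmMeans(upd$gmmS), gmmMeans(g), tolerance = 1e-10)
})

test_that("adapted means move toward a shifted patient under oracle labels", {
  # parameter-recovery property with oracle-confident probabilities
  # (0.999 on seizure epochs, 0.001 elsewhere) on 2-hour single-channel
  # records with shift scale 0.4, plus robustness to 10% label corruption
  # under the exp2 schedule: corruption shrinks the gain but the summed
  # distance to the shifted truth still improves
  successes <- 0L
  corruptStillImproves <- 0L
  corruptDegrades <- 0L
  valid <- 0L; s <- 0L
  sched <- sampleWeightSchedule("exp2", 10)
  part <- partitionProbabilitySpace(10)
  distTo <- function(fit, truth) {
    sqrt(sum((gmmMeans(fit) - gmmMeans(truth))^2))
  }
  while (valid < 20L) {
    s <- s + 1L
    cfg <- cohortConfig(nPatients = 1, hoursPerPatient = 2, D = 6,
                        nChannels = 1L, patientShiftScale = 0.4,
                        populationParams = list(sepDims = 4L),
                        seed = 300 + s)
    rec <- generateCohort(cfg)[[1]]
    tr <- recordTruth(rec)
    X <- epochFeatures(rec, 1)
    lab <- epochLabels(rec)
    if (!any(lab == 1)) next # a record without seizures cannot inform S
    valid <- valid + 1L
    pOracle <- ifelse(lab == 1, 0.999, 0.001)
    upd <- confidenceWeightedMapUpdate(tr$populationS, tr$populationNS, X,
                                       pOracle, sched, part)
    dS0 <- distTo(tr$populationS, tr$gmmS)
    dN0 <- distTo(tr$populationNS, tr$gmmNS)
    dS1 <- distTo(upd$gmmS, tr$gmmS)
    dN1 <- distTo(upd$gmmNS, tr$gmmNS)
    successes <- successes + (dS1 < dS0 && dN1 < dN0)

    set.seed(9000 + s)
    flip <- sample(length(pOracle), round(0.1 * length(pOracle)))
    pCorrupt <- pOracle
    pCorrupt[flip] <- 1 - pCorrupt[flip]
    updC <- confidenceWeightedMapUpdate(tr$populationS, tr$populationNS, X,
                                        pCorrupt, sched, part)
    dS1c <- distTo(updC$gmmS, tr$gmmS)
    dN1c <- distTo(updC$gmmNS, tr$gmmNS)
    corruptStillImproves <- corruptStillImproves +
      (dS1c + dN1c < dS0 + dN0)
    corruptDegrades <- corruptDegrades + (dS1c + dN1c > dS1 + dN1)
  }
  expect_gte(successes, 18L)
  expect_gte(corruptStillImproves, 16L)
  expect_gte(corruptDegrades, 18L)
})
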
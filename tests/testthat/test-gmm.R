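test_that("gaussian density matches closed forms and the product rule", {
  expect_equal(gaussianDensity(0, 0, 1), 1 / sqrt(2 * pi))
  expect_equal(gaussianDensity(1.5, 0.5, 1), exp(-0.5) / sqrt(2 * pi))
  expect_error(gaussianDensity(0, 0, -1), "positive")
  expect_error(gaussianDensity(c(0, 1), 0, 1), "mismatch")

  set.seed(4)
  x <- rnorm(3); mu <- rnorm(3); v <- runif(3, 0.2, 2)
  expect_equal(gaussianDensity(x, mu, v),
               prod(dnorm(x[1], mu[1], sqrt(v[1])),
                    dnorm(x[2], mu[2], sqrt(v[2])),
                    dnorm(x[3], mu[3], sqrt(v[3]))))
})

test_that("class log-likelihood is stable far into the tails", {
  g1 <- ClassGMM(matrix(0), 1, matrix(1), "NS")
  # single component: log-likelihood is the log density
  expect_equal(classLogLikelihood(0.7, g1), dnorm(0.7, log = TRUE))
  # two identical components collapse to one
  g2 <- ClassGMM(matrix(c(0, 0)), c(0.5, 0.5), matrix(c(1, 1)), "NS")
  expect_equal(classLogLikelihood(0.7, g2), classLogLikelihood(0.7, g1))
  # x where each component density ~ 1e-440: finite, matches the
  # log1p closed form for a two-component mixture
  g3 <- ClassGMM(matrix(c(0, 1)), c(0.5, 0.5), matrix(c(1, 1)), "NS")
  x <- 45
  la <- log(0.5) + dnorm(x, 0, 1, log = TRUE)
  lb <- log(0.5) + dnorm(x, 1, 1, log = TRUE)
  expect_true(is.finite(classLogLikelihood(x, g3)))
  expect_equal(classLogLikelihood(x, g3), lb + log1p(exp(la - lb)))
})

test_that("posterior is a proper complement and matches direct space", {
  g1 <- ClassGMM(matrix(1), 1, matrix(1), "S")
  g0 <- ClassGMM(matrix(0), 1, matrix(1), "NS")
  expect_equal(gmmPosterior(0.5, g1, g0, 0.5), 0.5)
  expect_lt(gmmPosterior(0.5, g1, g0, 1e-12), 1e-10)
  set.seed(9)
  for (r in 1:20) {
    gS <- randomGMMInstance(D = 2, tag = "S")
    gNS <- randomGMMInstance(D = 2, tag = "NS")
    x <- rnorm(2)
    prior <- runif(1, 0.05, 0.95)
    pS <- gmmPosterior(x, gS, gNS, prior)
    pNS <- gmmPosterior(x, gNS, gS, 1 - prior)
    expect_lt(abs(pS + pNS - 1), 1e-12)
    # direct-space posterior using raw densities
    lS <- exp(classLogLikelihood(x, gS))
    lNS <- exp(classLogLikelihood(x, gNS))
    expect_lt(abs(pS - prior * lS / (prior * lS + (1 - prior) * lNS)), 1e-10)
  }
})

test_that("EM recovers a single component in closed form", {
  set.seed(11)
  X <- matrix(rnorm(600, mean = 3, sd = 2), 200, 3)
  g <- fitGMM(X, 1, seed = 1)
  expect_equal(as.numeric(gmmMeans(g)), colMeans(X))
  mlVar <- colMeans(sweep(X, 2, colMeans(X))^2)
  expect_equal(as.numeric(gmmVariances(g)), mlVar, tolerance = 1e-8)
  expect_error(fitGMM(X, 500), "M > N")
})

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(12)
  X <- matrix(c(rnorm(2500, -2, 0.7), rnorm(2500, 2, 0.7)), ncol = 1)
  g <- fitGMM(X, 2, seed = 3)
  mu <- sort(as.numeric(gmmMeans(g)))
  expect_lt(abs(mu[1] + 2), 0.1)
  expect_lt(abs(mu[2] - 2), 0.1)
  # log-likelihood trace is monotone non-decreasing
  expect_true(all(diff(g@fitInfo$logLik) > -1e-8))
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(13)
  X <- matrix(c(rnorm(1500, -1.5), rnorm(1500, 1.5)), ncol = 1)
  g <- fitGMM(X, 2, seed = 3)
  mc <- mclust::Mclust(X, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(as.numeric(gmmMeans(g))),
               sort(as.numeric(mc$parameters$mean)), tolerance = 0.05)
  # our converged log-likelihood is not worse by more than a whisker
  expect_gt(max(g@fitInfo$logLik), mc$loglik - 1)
})

test_that("EM fits on several seeds keep the likelihood monotone", {
  set.seed(14)
  for (s in 1:5) {
    X <- matrix(rnorm(400 * 2, sd = 1.5), 400, 2) +
      matrix(sample(c(-1.5, 1.5), 800, TRUE), 400, 2)
    g <- fitGMM(X, 3, seed = s)
    expect_true(all(diff(g@fitInfo$logLik) > -1e-8))
  }
})
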
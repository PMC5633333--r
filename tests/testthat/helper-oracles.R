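# Independent brute-force oracles for the adaptation and evaluation maths.
# These deliberately avoid the package's log-space/vectorised code paths:
# densities are direct dnorm products, sums are explicit loops.

naiveDensity <- function(x, mean, var) prod(dnorm(x, mean, sqrt(var)))

naiveOccupancy <- function(x, means, weights, vars) {
  M <- nrow(means)
  d <- numeric(M)
  for (m in seq_len(M)) d[m] <- weights[m] * naiveDensity(x, means[m, ], vars[m, ])
  d / sum(d)
}

# occupancy-weighted data means E_m over a set of rows, by double loop
naiveStats <- function(X, means, weights, vars) {
  M <- nrow(means); D <- ncol(means)
  E <- matrix(0, M, D); mass <- numeric(M)
  for (i in seq_len(nrow(X))) {
    p <- naiveOccupancy(X[i, ], means, weights, vars)
    for (m in seq_len(M)) {
      E[m, ] <- E[m, ] + p[m] * X[i, ]
      mass[m] <- mass[m] + p[m]
    }
  }
  list(E = E, mass = mass)
}

naiveConventionalMap <- function(means, weights, vars, X, alpha, nIter = 3) {
  for (it in seq_len(nIter)) {
    st <- naiveStats(X, means, weights, vars)
    newMeans <- means
    for (m in seq_len(nrow(means))) {
      if (st$mass[m] > 0) {
        newMeans[m, ] <- alpha * means[m, ] + (1 - alpha) * st$E[m, ] / st$mass[m]
      }
    }
    means <- newMeans
  }
  means
}

# literal triple loop (component x cluster x point) of the confidence-
# weighted update for one class; empty/zero-mass clusters give their beta
# back to the original-model weight
naiveConfidenceMap <- function(means, weights, vars, X, clusterOf, alpha,
                               beta, K, nIter = 3) {
  M <- nrow(means); D <- ncol(means)
  for (it in seq_len(nIter)) {
    occ <- do.call(rbind, lapply(seq_len(nrow(X)), function(i) {
      naiveOccupancy(X[i, ], means, weights, vars)
    }))
    newMeans <- means
    for (m in seq_len(M)) {
      total <- rep(0, D)
      aEff <- alpha
      for (k in seq_len(K)) {
        I <- which(clusterOf == k)
        mass <- sum(occ[I, m])
        if (!length(I) || mass <= 0) {
          aEff <- aEff + beta[k]
          next
        }
        Ek <- rep(0, D)
        for (i in I) Ek <- Ek + occ[i, m] * X[i, ]
        total <- total + beta[k] * Ek / mass
      }
      newMeans[m, ] <- aEff * means[m, ] + total
    }
    means <- newMeans
  }
  means
}

naiveBin <- function(p, K) pmin(floor(p * K) + 1L, K)

# exhaustive pair-counting AUC with half credit for ties
naiveAuc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# fine-grid numerical integration of the empirical ROC over fpr in [0, 0.1].
# fpr is non-decreasing along the curve, so same-fpr vertices are contiguous
# (vertical rises of measure zero): between distinct fpr values the curve
# runs linearly from the highest tpr at the left node to the lowest at the
# right node.
naiveAuc90 <- function(probs, labels, n = 2e5) {
  cv <- rocCurve(probs, labels)
  fpr <- 1 - cv$specificity
  tpr <- cv$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  x <- unique(fpr)
  thi <- vapply(x, function(f) max(tpr[fpr == f]), numeric(1))
  tlo <- vapply(x, function(f) min(tpr[fpr == f]), numeric(1))
  evalRoc <- function(g) {
    i <- findInterval(g, x, rightmost.closed = TRUE)
    i <- pmin(i, length(x) - 1L)
    w <- (g - x[i]) / (x[i + 1L] - x[i])
    thi[i] + w * (tlo[i + 1L] - thi[i])
  }
  g <- seq(0, 0.1, length.out = n + 1)
  mid <- (head(g, -1) + tail(g, -1)) / 2
  mean(evalRoc(mid))
}

# a random small mixture instance for property tests
randomGMMInstance <- function(D = sample(1:3, 1), M = sample(1:4, 1),
                              tag = "NS") {
  means <- matrix(rnorm(M * D, sd = 2), M, D)
  vars <- matrix(runif(M * D, 0.3, 2), M, D)
  w <- runif(M, 0.2, 1)
  ClassGMM(means, w / sum(w), vars, classTag = tag)
}

# small cohort for pipeline tests (kept cheap)
tinyCohortConfig <- function(seed = 7, nPatients = 3, hours = 1.5, ...) {
  cohortConfig(nPatients = nPatients, hoursPerPatient = hours,
               D = 6, seed = seed,
               populationParams = list(sepDims = 4L), ...)
}

tinyExperimentConfig <- function(mode = "PI", seed = 5, ...) {
  experimentConfig(mode = mode, seed = seed, gmmComponents = 4L,
                   gmmMaxRows = 3000L,
                   svm = list(maxPerClass = 400L), ...)
}
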
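#' Multivariate diagonal Gaussian density
#'
#' Density of a single point under one Gaussian component with diagonal
#' covariance. For D independent dimensions the density is the product of
#' the univariate densities.
#'
#' @param x numeric D-vector.
#' @param mean numeric D-vector.
#' @param var numeric D-vector of positive variances.
#' @return scalar density g(x | mean, var) >= 0.
#' @export
gaussianDensity <- function(x, mean, var) {
  if (length(x) != length(mean) || length(mean) != length(var)) {
    stop("dimension mismatch between x, mean and var")
  }
  if (any(var <= 0)) stop("variances must be positive")
  exp(logGaussianDensity(matrix(x, nrow = 1), mean, var))
}

# per-row log density of X (N x D) under one diagonal Gaussian
logGaussianDensity <- function(X, mean, var) {
  cst <- -0.5 * sum(log(2 * pi * var))
  z <- sweep(X, 2L, mean, "-")
  cst - 0.5 * as.numeric(z^2 %*% (1 / var))
}

# N x M matrix of log(w_m) + log g(x_i | mu_m, Sigma_m); expands the
# quadratic form so all components are evaluated with two matrix products
componentLogDensities <- function(X, gmm) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  iv <- 1 / gmm@variances                      # M x D
  quad <- X^2 %*% t(iv) - 2 * (X %*% t(gmm@means * iv))
  cst <- log(gmm@weights) -
    0.5 * (rowSums(gmm@means^2 * iv) + rowSums(log(2 * pi * gmm@variances)))
  sweep(-0.5 * quad, 2L, cst, "+")
}

#' Class log-likelihood under a mixture
#'
#' log sum_j w_j g(x | mu_j, Sigma_j), evaluated with log-sum-exp so that
#' per-component densities spanning hundreds of orders of magnitude still
#' give a finite result.
#'
#' @param X numeric matrix (epochs x features) or a single D-vector.
#' @param gmm a \linkS4class{ClassGMM}.
#' @return numeric vector of per-row log mixture densities.
#' @export
classLogLikelihood <- function(X, gmm) {
  rowLogSumExp(componentLogDensities(X, gmm))
}

#' Posterior seizure probability from the generative branch
#'
#' Bayes posterior P(S | x) = prior * L_S / (prior * L_S + (1-prior) * L_NS)
#' computed entirely in log space.
#'
#' @param X numeric matrix (epochs x features) or a single D-vector.
#' @param gmmS,gmmNS seizure / non-seizure \linkS4class{ClassGMM} models.
#' @param priorS prior seizure probability in (0,1); default 0.5 (class
#'   balance is handled by the evaluation, not the prior).
#' @return numeric vector of posterior seizure probabilities in [0,1].
#' @export
gmmPosterior <- function(X, gmmS, gmmNS, priorS = 0.5) {
  stopifnot(priorS > 0, priorS < 1)
  llS <- classLogLikelihood(X, gmmS)
  llNS <- classLogLikelihood(X, gmmNS)
  plogis(llS - llNS + qlogis(priorS))
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' Expectation-maximisation from a k-means-seeded initialisation, with a
#' per-dimension variance floor of \code{varFloorFactor} times the feature
#' variance. The per-iteration log-likelihood trace is stored in
#' \code{fitInfo} and is non-decreasing.
#'
#' @param X numeric matrix, rows are observations.
#' @param M number of mixture components (>= 1, <= nrow(X)).
#' @param classTag "S" or "NS".
#' @param seed integer seed for the k-means initialisation.
#' @param tol EM stops when the mean per-observation log-likelihood
#'   improves by less than this amount between iterations (default 1e-7).
#' @param maxIter maximum EM iterations.
#' @param varFloorFactor variance floor as a fraction of each feature's
#'   variance (default 1e-6).
#' @return a \linkS4class{ClassGMM}; \code{fitInfo} holds \code{logLik}
#'   (trace) and \code{iterations}.
#' @export
fitGMM <- function(X, M, classTag = "NS", seed = 1L, tol = 1e-7,
                   maxIter = 100L, varFloorFactor = 1e-6) {
  X <- as.matrix(X)
  N <- nrow(X); D <- ncol(X)
  if (M < 1L) stop("M must be >= 1")
  if (M > N) stop("more components than data rows (M > N)")
  colVar <- apply(X, 2L, var)
  colVar[!is.finite(colVar) | colVar <= 0] <- 1
  floorVec <- pmax(varFloorFactor * colVar, .Machine$double.xmin)

  init <- withSeed(seed, {
    if (M == 1L) {
      list(centers = matrix(colMeans(X), 1))
    } else {
      suppressWarnings(kmeans(X, centers = M, nstart = 3L, iter.max = 50L))
    }
  })
  means <- matrix(init$centers, M, D)
  vars <- matrix(rep(pmax(colVar, floorVec), each = M), M, D)
  weights <- rep(1 / M, M)
  gmm <- ClassGMM(means, weights, vars, classTag = classTag)

  llTrace <- numeric(0)
  llOld <- -Inf
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    # E step
    lcomp <- componentLogDensities(X, gmm)
    lse <- rowLogSumExp(lcomp)
    ll <- sum(lse)
    llTrace <- c(llTrace, ll)
    resp <- exp(lcomp - lse)
    # M step
    Nk <- colSums(resp)
    if (any(Nk < 1e-10)) {
      warning("collapsed mixture component; re-seeding at a data point")
      for (m in which(Nk < 1e-10)) {
        i <- withSeed(seed + it + m, sample.int(N, 1L))
        gmm@means[m, ] <- X[i, ]
        gmm@variances[m, ] <- pmax(colVar, floorVec)
        resp[, m] <- 1 / M
      }
      resp <- resp / rowSums(resp)
      Nk <- colSums(resp)
    }
    weights <- Nk / N
    means <- t(resp) %*% X / Nk
    ex2 <- t(resp) %*% X^2 / Nk
    vars <- ex2 - means^2
    vars <- pmax(vars, matrix(rep(floorVec, each = M), M, D))
    gmm@means <- means
    gmm@weights <- weights / sum(weights)
    gmm@variances <- vars
    if (is.finite(llOld) && (ll - llOld) / N < tol) break
    llOld <- ll
  }
  gmm@fitInfo <- list(logLik = llTrace, iterations = it,
                      varianceFloor = floorVec)
  validObject(gmm)
  gmm
}

#' Draw samples from a ClassGMM
#'
#' @param gmm a \linkS4class{ClassGMM}.
#' @param n number of draws.
#' @return n x D numeric matrix.
#' @export
sampleGMM <- function(gmm, n) {
  M <- nComponents(gmm)
  D <- ncol(gmm@means)
  comp <- sample.int(M, n, replace = TRUE, prob = gmm@weights)
  z <- matrix(rnorm(n * D), n, D)
  gmm@means[comp, , drop = FALSE] +
    z * sqrt(gmm@variances[comp, , drop = FALSE])
}

#' Serialize a ClassGMM to a versioned JSON container
#'
#' All parameters are written at full floating-point precision so that a
#' write/read roundtrip is bit-exact.
#'
#' @param gmm a \linkS4class{ClassGMM}.
#' @param path output file path.
#' @param history optional adaptation-history list (hours adapted, schedule
#'   used) stored alongside the parameters.
#' @return \code{path}, invisibly.
#' @export
writeGMM <- function(gmm, path, history = NULL) {
  # parameters are stored as 17-significant-digit strings: decimal JSON
  # numbers would lose the last ulp, strings round-trip doubles exactly
  obj <- list(
    format = "seizAdapt-gmm",
    version = "1",
    classTag = gmm@classTag,
    M = nComponents(gmm),
    D = ncol(gmm@means),
    weights = fmtFull(gmm@weights),
    means = fmtFull(as.numeric(gmm@means)),
    variances = fmtFull(as.numeric(gmm@variances)),
    history = history
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a ClassGMM from its JSON container
#' @param path file written by \code{\link{writeGMM}}.
#' @return a \linkS4class{ClassGMM}; any adaptation history is kept in
#'   \code{fitInfo$history}.
#' @export
readGMM <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "seizAdapt-gmm")) {
    stop("not a seizAdapt GMM container: ", path)
  }
  # new() rather than the constructor: re-normalising the weights could
  # perturb the stored values by an ulp
  new("ClassGMM", classTag = obj$classTag,
      means = matrix(as.numeric(obj$means), obj$M, obj$D),
      weights = as.numeric(obj$weights),
      variances = matrix(as.numeric(obj$variances), obj$M, obj$D),
      fitInfo = list(history = obj$history))
}
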
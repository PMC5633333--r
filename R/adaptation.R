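#' Occupational likelihood (component responsibilities)
#'
#' Posterior probability that each feature vector was generated by each
#' component of a class mixture:
#' P_{C,m}(x_i) = w_m g(x_i | mu_m, Sigma_m) / sum_j w_j g(x_i | mu_j,
#' Sigma_j), computed in log space and normalised row-wise.
#'
#' @param X numeric matrix (N x D) or single D-vector.
#' @param gmm a \linkS4class{ClassGMM}.
#' @return N x M matrix; each row is non-negative and sums to 1. Rows where
#'   every component density underflows to zero get uniform
#'   responsibilities, with a warning.
#' @export
occupationalLikelihood <- function(X, gmm) {
  lcomp <- componentLogDensities(X, gmm)
  lse <- rowLogSumExp(lcomp)
  bad <- !is.finite(lse)
  resp <- exp(lcomp - lse)
  if (any(bad)) {
    warning("all component densities numerically zero for ", sum(bad),
            " row(s); using uniform responsibilities")
    resp[bad, ] <- 1 / nComponents(gmm)
  }
  resp
}

# occupancy-weighted data means and masses for all components:
# list(E = M x D matrix (NA rows where mass == 0), mass = length-M vector)
adaptationStats <- function(X, gmm, resp = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (is.null(resp)) resp <- occupationalLikelihood(X, gmm)
  mass <- colSums(resp)
  E <- t(resp) %*% X
  E <- sweep(E, 1L, mass, "/")
  E[mass <= 0, ] <- NA_real_
  list(E = E, mass = mass)
}

#' Occupancy-weighted mean of adaptation data
#'
#' E_{C,m}(X) = sum_i P_{C,m}(x_i) x_i / sum_i P_{C,m}(x_i) for one
#' component m.
#'
#' @param X numeric matrix (subset of adaptation data, N x D).
#' @param gmm a \linkS4class{ClassGMM}.
#' @param m component index.
#' @return numeric D-vector; all-NA with attribute \code{undefined = TRUE}
#'   when the total occupancy mass is zero (caller must skip the update).
#' @export
weightedDataMean <- function(X, gmm, m) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (nrow(X) == 0L) stop("subset is empty")
  st <- adaptationStats(X, gmm)
  out <- st$E[m, ]
  if (st$mass[m] <= 0) attr(out, "undefined") <- TRUE
  out
}

#' Conventional MAP adaptation of mixture means
#'
#' Iteratively interpolates every component mean with the occupancy-weighted
#' data mean: mu_m <- alpha mu_m + (1 - alpha) E_m(X), recomputing the
#' occupancies from the updated means each pass (3 passes by default).
#' Weights and covariances are left untouched.
#'
#' @param gmm a \linkS4class{ClassGMM}.
#' @param X adaptation data (N x D).
#' @param alpha original-model weight in [0,1].
#' @param nIter number of passes (default 3).
#' @return the adapted \linkS4class{ClassGMM}.
#' @export
conventionalMapUpdate <- function(gmm, X, alpha, nIter = 3L) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (nrow(X) == 0L) {
    warning("empty adaptation set; model returned unchanged")
    return(gmm)
  }
  for (it in seq_len(nIter)) {
    st <- adaptationStats(X, gmm)
    upd <- st$mass > 0
    gmm@means[upd, ] <- alpha * gmm@means[upd, , drop = FALSE] +
      (1 - alpha) * st$E[upd, , drop = FALSE]
  }
  gmm
}

#' Partition the probability space into equal-width bins
#'
#' K non-overlapping bins [(k-1)/K, k/K) covering [0,1], the last bin
#' closed at 1.
#'
#' @param K number of bins (>= 1).
#' @return a \linkS4class{ClusterPartition}.
#' @export
partitionProbabilitySpace <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be >= 1")
  new("ClusterPartition", K = K,
      lower = (seq_len(K) - 1L) / K, upper = seq_len(K) / K)
}

# bin index of each probability under a partition (last bin closed at 1)
binIndex <- function(p, partition) {
  idx <- findInterval(p, partition@lower)
  pmin(pmax(idx, 1L), partition@K)
}

#' Assign epochs to confidence clusters
#'
#' Seizure-model clusters collect indices by the discriminative seizure
#' probability (i in I_S,k iff lower_k <= P_i < upper_k); non-seizure
#' clusters use the complementary rule on 1 - P_i. Each class's K sets
#' partition all N indices.
#'
#' @param pSvm a \linkS4class{ProbabilitySeries} or numeric vector in [0,1].
#' @param partition a \linkS4class{ClusterPartition}.
#' @return list with elements \code{IS} and \code{INS}, each a length-K
#'   list of integer index vectors.
#' @export
assignClusters <- function(pSvm, partition) {
  p <- if (is(pSvm, "ProbabilitySeries")) probValues(pSvm) else pSvm
  stopifnot(all(p >= 0 & p <= 1))
  K <- partition@K
  kS <- binIndex(p, partition)
  kNS <- binIndex(1 - p, partition)
  idx <- seq_along(p)
  list(IS = lapply(seq_len(K), function(k) idx[kS == k]),
       INS = lapply(seq_len(K), function(k) idx[kNS == k]))
}

# the four monotone weight functions over confidence c in [0,1]
weightFunction <- function(kind, params = list()) {
  prm <- modifyList(list(slope = 1, steepness = 10, decay1 = 3, decay2 = 8),
                    params)
  switch(kind,
    linear = function(c) prm$slope * c,
    sigmoid = function(c) 1 / (1 + exp(-prm$steepness * (c - 0.5))),
    exp1 = function(c) exp(-prm$decay1 * (1 - c)),
    exp2 = function(c) exp(-prm$decay2 * (1 - c)),
    stop("unknown schedule kind: ", kind)
  )
}

#' Sample and normalise a confidence weight schedule
#'
#' Samples a monotone weight function at the K bin centres to give raw
#' weights h_k, then normalises together with the original-data mass hbar
#' to a partition of unity: beta_k = h_k / (hbar + sum(h)),
#' alpha = hbar / (hbar + sum(h)). The original-model weight alpha must be
#' the largest weight; parameters violating this (or monotonicity) raise an
#' error.
#'
#' @param kind "linear", "sigmoid", "exp1" or "exp2".
#' @param K number of clusters.
#' @param params shape parameters: \code{slope} (linear), \code{steepness}
#'   (sigmoid, default 10), \code{decay1} (exp1, default 3), \code{decay2}
#'   (exp2, default 8).
#' @param hbar original-data mass; default \code{sum(h)}, giving
#'   alpha = 0.5.
#' @return a \linkS4class{WeightSchedule}.
#' @export
sampleWeightSchedule <- function(kind = c("exp2", "linear", "sigmoid",
                                          "exp1"),
                                 K = 10L, params = list(), hbar = NULL) {
  kind <- match.arg(kind)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  f <- weightFunction(kind, params)
  centres <- (seq_len(K) - 0.5) / K
  h <- f(centres)
  if (any(h < 0)) stop("weight function must be non-negative")
  if (any(diff(h) < -1e-12)) stop("weight function must be non-decreasing")
  if (sum(h) <= 0) stop("weight function is identically zero on [0,1]")
  if (is.null(hbar)) hbar <- sum(h)
  if (hbar <= 0) stop("hbar must be positive")
  if (is.infinite(hbar)) { # alpha = 1 limit: adaptation disabled
    beta <- rep(0, K)
    alpha <- 1
  } else {
    denom <- hbar + sum(h)
    beta <- h / denom
    alpha <- hbar / denom
  }
  sched <- new("WeightSchedule", kind = kind,
               params = modifyList(list(), params), h = h, hbar = hbar,
               beta = beta, alpha = alpha)
  validObject(sched)
  sched
}

#' Confidence-weighted MAP adaptation of both class models
#'
#' The core patient-adaptation update. The adaptation data X are grouped
#' into K confidence clusters by their discriminative seizure probability
#' (complementary rule for the non-seizure model); each component mean is
#' then updated as
#' mu_{C,m} <- alpha mu_{C,m} + sum_k beta_k E_{C,m,k}, where E_{C,m,k} is
#' the occupancy-weighted mean of the cluster-k data. Both class models are
#' adapted simultaneously from the same data. Clusters that are empty (or
#' have zero occupancy mass for a component) contribute nothing and their
#' beta is folded back into alpha for that component, conserving total
#' mass 1. Three passes are made by default, recomputing occupancies from
#' the updated means while keeping the cluster assignment and beta fixed
#' (they depend only on the discriminative probabilities, which do not
#' change).
#'
#' @param gmmS,gmmNS seizure / non-seizure \linkS4class{ClassGMM} models.
#' @param X pooled adaptation feature vectors (N x D).
#' @param pSvm discriminative seizure probabilities aligned to the rows of
#'   X (\linkS4class{ProbabilitySeries} or numeric vector).
#' @param schedule a \linkS4class{WeightSchedule}.
#' @param partition a \linkS4class{ClusterPartition} with the same K.
#' @param nIter number of passes (default 3).
#' @return list with adapted \code{gmmS} and \code{gmmNS}.
#' @export
confidenceWeightedMapUpdate <- function(gmmS, gmmNS, X, pSvm, schedule,
                                        partition, nIter = 3L) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  p <- if (is(pSvm, "ProbabilitySeries")) probValues(pSvm) else pSvm
  if (length(schedule@beta) != partition@K) {
    stop("schedule and partition disagree on K")
  }
  if (nrow(X) == 0L) {
    warning("empty adaptation set; models returned unchanged")
    return(list(gmmS = gmmS, gmmNS = gmmNS))
  }
  if (length(p) != nrow(X)) stop("pSvm length must match nrow(X)")
  sets <- assignClusters(p, partition)
  list(gmmS = adaptClassMeans(gmmS, X, sets$IS, schedule, nIter),
       gmmNS = adaptClassMeans(gmmNS, X, sets$INS, schedule, nIter))
}

# one class's confidence-weighted mean update (fixed clusters and beta)
adaptClassMeans <- function(gmm, X, idxSets, schedule, nIter) {
  alpha <- schedule@alpha
  beta <- schedule@beta
  K <- length(beta)
  M <- nComponents(gmm)
  D <- ncol(gmm@means)
  for (it in seq_len(nIter)) {
    resp <- occupationalLikelihood(X, gmm)
    contrib <- matrix(0, M, D)
    fold <- rep(0, M) # beta mass of clusters contributing nothing
    for (k in seq_len(K)) {
      I <- idxSets[[k]]
      if (!length(I)) {
        fold <- fold + beta[k]
        next
      }
      rk <- resp[I, , drop = FALSE]
      mass <- colSums(rk)
      Ek <- t(rk) %*% X[I, , drop = FALSE]
      ok <- mass > 0
      Ek[ok, ] <- Ek[ok, , drop = FALSE] / mass[ok]
      contrib[ok, ] <- contrib[ok, , drop = FALSE] +
        beta[k] * Ek[ok, , drop = FALSE]
      fold[!ok] <- fold[!ok] + beta[k]
    }
    gmm@means <- (alpha + fold) * gmm@means + contrib
  }
  gmm
}
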
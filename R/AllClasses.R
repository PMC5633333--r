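#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assays colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom stats var cov rnorm runif rpois dnorm sd kmeans glm binomial
#'   coef predict plogis qlogis pnorm quantile setNames
#' @importFrom utils head tail count.fields read.csv write.csv packageVersion
#'   modifyList
NULL

#' FeatureRecord: an epoch-indexed multichannel feature stream
#'
#' A \code{FeatureRecord} holds the per-epoch feature vectors of one
#' patient's EEG recording, one assay per channel (features x epochs),
#' together with per-epoch seizure annotations and epoch start times.
#' It extends \linkS4class{SummarizedExperiment}: \code{colData} carries
#' the binary \code{label} (1 = seizure) and \code{t_start} (seconds from
#' record start) of every epoch.
#'
#' @slot patientID single character identifier.
#' @slot epochDuration epoch window length in seconds.
#' @slot epochHop hop between consecutive epoch starts in seconds.
#'
#' @details Epoch times must be strictly increasing with a constant step
#' equal to \code{epochHop}; all channels share the same number of epochs
#' and feature dimension; feature values must be finite (readers drop and
#' log rows containing NaN).
#'
#' @export
setClass("FeatureRecord",
  contains = "SummarizedExperiment",
  slots = c(
    patientID = "character",
    epochDuration = "numeric",
    epochHop = "numeric"
  )
)

setValidity("FeatureRecord", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assays(object)
  if (length(a) < 1L) msg <- c(msg, "at least one channel assay is required")
  dims <- vapply(as.list(a), function(m) dim(m), integer(2))
  if (length(a) >= 1L && any(dims != dims[, 1])) {
    msg <- c(msg, "all channels must have identical dimensions")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("label", "t_start") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'label' and 't_start'")
  } else {
    if (!all(cd$label %in% c(0, 1))) msg <- c(msg, "labels must be 0/1")
    ts <- cd$t_start
    if (length(ts) > 1) {
      d <- diff(ts)
      if (any(d <= 0)) msg <- c(msg, "t_start must be strictly increasing")
      if (max(abs(d - object@epochHop)) > 1e-9) {
        msg <- c(msg, "t_start step must equal epochHop")
      }
    }
  }
  for (m in as.list(a)) {
    if (any(is.nan(m))) { msg <- c(msg, "feature values must not be NaN"); break }
  }
  if (length(object@patientID) != 1L) msg <- c(msg, "patientID must be length 1")
  if (object@epochDuration <= 0 || object@epochHop <= 0) {
    msg <- c(msg, "epochDuration and epochHop must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureRecord
#'
#' @param features named list of numeric matrices, one per channel, each
#'   epochs x features (they are stored transposed, features x epochs, as
#'   SummarizedExperiment assays).
#' @param labels integer/numeric vector of per-epoch 0/1 annotations.
#' @param tStart numeric vector of epoch start times (s).
#' @param patientID character scalar.
#' @param epochDuration,epochHop epoch geometry in seconds.
#' @param truth optional list of generating parameters (kept in metadata
#'   for parameter-recovery experiments on synthetic data).
#' @return a \linkS4class{FeatureRecord}.
#' @export
FeatureRecord <- function(features, labels, tStart, patientID,
                          epochDuration = 8, epochHop = 4, truth = NULL) {
  if (is.null(names(features)) || any(!nzchar(names(features)))) {
    names(features) <- paste0("ch", seq_along(features))
  }
  assays <- lapply(features, function(m) {
    m <- as.matrix(m)
    t(m) # store features x epochs
  })
  d <- nrow(assays[[1]])
  for (i in seq_along(assays)) {
    rownames(assays[[i]]) <- paste0("f", seq_len(d))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(label = as.numeric(labels),
                                   t_start = as.numeric(tStart))
  )
  md <- S4Vectors::metadata(se)
  md$truth <- truth
  S4Vectors::metadata(se) <- md
  new("FeatureRecord", se, patientID = as.character(patientID),
      epochDuration = epochDuration, epochHop = epochHop)
}

#' ClassGMM: a per-class Gaussian mixture
#'
#' Diagonal-covariance Gaussian mixture parameterising one class-conditional
#' feature density (seizure "S" or non-seizure "NS"): component means, mixing
#' weights and per-dimension variances.
#'
#' @slot classTag "S" or "NS".
#' @slot means M x D matrix of component means.
#' @slot weights length-M mixing weights, summing to 1.
#' @slot variances M x D matrix of per-dimension variances (all > 0).
#' @slot fitInfo list of fitting diagnostics (log-likelihood trace, etc.).
#' @export
setClass("ClassGMM",
  slots = c(classTag = "character", means = "matrix", weights = "numeric",
            variances = "matrix", fitInfo = "list")
)

setValidity("ClassGMM", function(object) {
  msg <- character()
  M <- nrow(object@means)
  if (M < 1L) msg <- c(msg, "at least one component required")
  if (length(object@weights) != M) msg <- c(msg, "weights length must equal M")
  if (any(object@weights <= 0) || any(object@weights > 1)) {
    msg <- c(msg, "weights must lie in (0,1]")
  }
  if (abs(sum(object@weights) - 1) > 1e-10) {
    msg <- c(msg, "weights must sum to 1 (tol 1e-10)")
  }
  if (!all(dim(object@variances) == dim(object@means))) {
    msg <- c(msg, "variances must match means in shape")
  }
  if (any(object@variances <= 0)) msg <- c(msg, "variances must be positive")
  if (!object@classTag %in% c("S", "NS")) {
    msg <- c(msg, "classTag must be 'S' or 'NS'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ClassGMM
#'
#' @param means M x D matrix (a vector is taken as a single D-vector mean).
#' @param weights length-M mixing weights; normalised to sum to 1.
#' @param variances M x D matrix of positive variances.
#' @param classTag "S" (seizure) or "NS" (non-seizure).
#' @param fitInfo optional list of diagnostics.
#' @return a \linkS4class{ClassGMM}.
#' @export
ClassGMM <- function(means, weights, variances, classTag = "NS",
                     fitInfo = list()) {
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  if (is.null(dim(variances))) variances <- matrix(variances, nrow = 1)
  new("ClassGMM", classTag = classTag, means = means,
      weights = as.numeric(weights) / sum(weights),
      variances = variances, fitInfo = fitInfo)
}

#' ProbabilitySeries: per-epoch seizure probabilities
#'
#' @slot values numeric vector of probabilities in [0,1], one per epoch.
#' @slot sourceTag which branch produced it: "SVM", "GMM" or "FUSION".
#' @export
setClass("ProbabilitySeries",
  slots = c(values = "numeric", sourceTag = "character")
)

setValidity("ProbabilitySeries", function(object) {
  msg <- character()
  if (any(object@values < 0 | object@values > 1, na.rm = FALSE)) {
    msg <- c(msg, "all values must lie in [0,1]")
  }
  if (!object@sourceTag %in% c("SVM", "GMM", "FUSION")) {
    msg <- c(msg, "sourceTag must be one of SVM, GMM, FUSION")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProbabilitySeries
#' @param values numeric probabilities in [0,1].
#' @param sourceTag "SVM", "GMM" or "FUSION".
#' @return a \linkS4class{ProbabilitySeries}.
#' @export
ProbabilitySeries <- function(values, sourceTag) {
  new("ProbabilitySeries", values = as.numeric(values), sourceTag = sourceTag)
}

#' ClusterPartition: non-overlapping probability bins
#'
#' K disjoint intervals [lower_k, upper_k) covering [0,1]; the last bin is
#' closed at 1 so every probability belongs to exactly one bin.
#'
#' @slot K number of bins.
#' @slot lower,upper length-K bin limits.
#' @export
setClass("ClusterPartition",
  slots = c(K = "integer", lower = "numeric", upper = "numeric")
)

setValidity("ClusterPartition", function(object) {
  msg <- character()
  K <- object@K
  if (K < 1L) msg <- c(msg, "K must be >= 1")
  if (length(object@lower) != K || length(object@upper) != K) {
    msg <- c(msg, "lower/upper must have length K")
  } else {
    if (abs(object@lower[1]) > 1e-12) msg <- c(msg, "first bin must start at 0")
    if (abs(object@upper[K] - 1) > 1e-12) msg <- c(msg, "last bin must end at 1")
    if (any(object@lower >= object@upper)) msg <- c(msg, "bins must be non-empty")
    if (K > 1 && max(abs(object@upper[-K] - object@lower[-1])) > 1e-12) {
      msg <- c(msg, "bins must tile [0,1] without gaps or overlaps")
    }
  }
  if (length(msg)) msg else TRUE
})

#' WeightSchedule: sampled, normalised confidence-cluster weights
#'
#' A monotone weight function sampled at the K bin centres gives raw weights
#' h_k; together with the original-data mass hbar they are normalised to a
#' partition of unity: beta_k = h_k / (hbar + sum(h)) and
#' alpha = hbar / (hbar + sum(h)) = 1 - sum(beta). The original-model weight
#' alpha is required to dominate every beta_k.
#'
#' @slot kind "linear", "sigmoid", "exp1" or "exp2".
#' @slot params shape parameters of the weight function.
#' @slot h raw sampled weights (length K).
#' @slot hbar original-data mass (scalar > 0).
#' @slot beta normalised cluster weights (length K).
#' @slot alpha original-model weight.
#' @export
setClass("WeightSchedule",
  slots = c(kind = "character", params = "list", h = "numeric",
            hbar = "numeric", beta = "numeric", alpha = "numeric")
)

setValidity("WeightSchedule", function(object) {
  msg <- character()
  if (!object@kind %in% c("linear", "sigmoid", "exp1", "exp2"))
    msg <- c(msg, "unknown schedule kind")
  if (any(object@h < 0)) msg <- c(msg, "h must be non-negative")
  if (any(diff(object@h) < -1e-12)) msg <- c(msg, "h must be non-decreasing")
  if (object@hbar <= 0) msg <- c(msg, "hbar must be positive")
  if (abs(object@alpha + sum(object@beta) - 1) > 1e-12) {
    msg <- c(msg, "alpha + sum(beta) must equal 1 (tol 1e-12)")
  }
  if (object@alpha <= max(object@beta)) {
    msg <- c(msg, "alpha must exceed every beta_k")
  }
  if (length(msg)) msg else TRUE
})
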
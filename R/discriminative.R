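#' CalibrationMap: Platt-style sigmoid score calibration
#'
#' Monotone non-decreasing map from a raw margin score to a probability:
#' p = plogis(intercept + slope * score), slope >= 0.
#'
#' @slot intercept,slope sigmoid coefficients.
#' @export
setClass("CalibrationMap",
  slots = c(intercept = "numeric", slope = "numeric"))

setValidity("CalibrationMap", function(object) {
  if (object@slope < 0) "slope must be non-negative (monotone map)" else TRUE
})

#' DiscriminativeModel: fixed patient-independent margin classifier
#'
#' A kernel margin classifier trained on standardized per-epoch features,
#' bundled with its feature standardization statistics and its sigmoid
#' probability calibration.
#'
#' @slot fit the underlying svm fit.
#' @slot calibration a \linkS4class{CalibrationMap}.
#' @slot center,scale training-set standardization statistics.
#' @slot flipSign whether raw decision values are negated so that larger
#'   means more seizure-like.
#' @slot config training configuration used.
#' @export
setClass("DiscriminativeModel",
  slots = c(fit = "ANY", calibration = "CalibrationMap",
            center = "numeric", scale = "numeric", flipSign = "logical",
            config = "list")
)

#' Fit the sigmoid calibration map
#'
#' Maximum-likelihood logistic fit of the labels on the raw scores
#' (Platt scaling). The fitted map is monotone non-decreasing, so applying
#' it preserves the ranking of the raw scores.
#'
#' @param rawScores numeric decision scores.
#' @param labels binary 0/1 vector aligned to the scores.
#' @return a \linkS4class{CalibrationMap}.
#' @export
calibrate <- function(rawScores, labels) {
  stopifnot(length(rawScores) == length(labels),
            all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to calibrate")
  }
  if (diff(range(rawScores)) < 1e-12) {
    stop("degenerate (constant) scores cannot be calibrated")
  }
  fit <- suppressWarnings(
    glm(labels ~ rawScores, family = binomial()))
  co <- coef(fit)
  if (!all(is.finite(co))) stop("calibration fit failed")
  if (co[2] < 0) {
    stop("scores are anti-ordered with the labels; orient scores first")
  }
  new("CalibrationMap", intercept = unname(co[1]), slope = unname(co[2]))
}

#' Apply a calibration map to raw scores
#' @param map a \linkS4class{CalibrationMap}.
#' @param scores numeric raw scores.
#' @param eps clamp margin (default 1e-6).
#' @return probabilities in [eps, 1-eps].
#' @export
applyCalibration <- function(map, scores, eps = 1e-6) {
  clampProbs(plogis(map@intercept + map@slope * scores), eps)
}

# raw decision values oriented so larger = more seizure-like
decisionValues <- function(fit, X, flipSign) {
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  dv <- as.numeric(dv)
  if (flipSign) -dv else dv
}

#' Train the patient-independent discriminative classifier
#'
#' Standardizes the features by the training-set statistics, draws a
#' class-balanced training subsample (at most \code{maxPerClass} epochs per
#' class), trains an RBF-kernel support vector machine, and fits the Platt
#' sigmoid on cross-validated decision scores (\code{calibFolds} folds) so
#' the calibration is not fitted on in-sample margins. Deterministic given
#' \code{seed}.
#'
#' @param X numeric matrix of per-epoch features (rows pooled over
#'   patients/channels).
#' @param labels binary 0/1 vector.
#' @param config list: \code{kernel} ("radial"), \code{cost} (1),
#'   \code{gamma} (default 1/D), \code{maxPerClass} (1000),
#'   \code{calibFolds} (2).
#' @param seed integer seed (subsampling and fold assignment).
#' @return a \linkS4class{DiscriminativeModel}.
#' @export
fitDiscriminative <- function(X, labels, config = list(), seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in the training data")
  }
  cfg <- modifyList(list(kernel = "radial", cost = 1, gamma = NULL,
                         maxPerClass = 1000L, calibFolds = 2L), config)
  if (is.null(cfg$gamma)) cfg$gamma <- 1 / ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")

  withSeed(seed, {
    keep <- unlist(lapply(c(0, 1), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > cfg$maxPerClass) {
        sample(idx, cfg$maxPerClass)
      } else idx
    }))
    keep <- sort(keep)
    Xt <- Xs[keep, , drop = FALSE]
    yt <- labels[keep]
    yf <- factor(yt, levels = c(0, 1))

    fit <- e1071::svm(Xt, yf, kernel = cfg$kernel, cost = cfg$cost,
                      gamma = cfg$gamma, scale = FALSE)
    # orient decision values toward the seizure class
    dv <- as.numeric(attr(predict(fit, Xt, decision.values = TRUE),
                          "decision.values"))
    flip <- mean(dv[yt == 1]) < mean(dv[yt == 0])

    # out-of-fold decision scores for the Platt fit
    nF <- max(2L, cfg$calibFolds)
    folds <- sample(rep_len(seq_len(nF), nrow(Xt)))
    cvScores <- numeric(nrow(Xt))
    for (f in seq_len(nF)) {
      tr <- folds != f
      if (length(unique(yt[tr])) < 2L) { # degenerate fold: use full-fit scores
        cvScores[!tr] <- decisionValues(fit, Xt[!tr, , drop = FALSE], flip)
        next
      }
      sub <- e1071::svm(Xt[tr, , drop = FALSE], yf[tr], kernel = cfg$kernel,
                        cost = cfg$cost, gamma = cfg$gamma, scale = FALSE)
      sdv <- as.numeric(attr(predict(sub, Xt[tr, , drop = FALSE],
                                     decision.values = TRUE),
                             "decision.values"))
      sflip <- mean(sdv[yt[tr] == 1]) < mean(sdv[yt[tr] == 0])
      cvScores[!tr] <- decisionValues(sub, Xt[!tr, , drop = FALSE], sflip)
    }
    cal <- calibrate(cvScores, yt)
    new("DiscriminativeModel", fit = fit, calibration = cal,
        center = ctr, scale = scl, flipSign = flip, config = cfg)
  })
}

#' Calibrated per-channel seizure probabilities
#'
#' Applies the discriminative model and its calibration to every channel
#' of a record; outputs are clamped to [1e-6, 1 - 1e-6] so that no branch
#' can permanently zero the geometric-mean fusion.
#'
#' @param model a \linkS4class{DiscriminativeModel}.
#' @param record a \linkS4class{FeatureRecord} (or a plain feature matrix).
#' @return for a record, a list of per-channel
#'   \linkS4class{ProbabilitySeries} tagged "SVM"; for a matrix, a single
#'   ProbabilitySeries.
#' @export
predictProba <- function(model, record) {
  scoreMatrix <- function(X) {
    if (ncol(X) != length(model@center)) {
      stop("feature dimension mismatch: model expects ",
           length(model@center), ", got ", ncol(X))
    }
    Xs <- sweep(sweep(X, 2L, model@center, "-"), 2L, model@scale, "/")
    dv <- decisionValues(model@fit, Xs, model@flipSign)
    ProbabilitySeries(applyCalibration(model@calibration, dv), "SVM")
  }
  if (is(record, "FeatureRecord")) {
    out <- lapply(seq_len(nChannels(record)), function(ch) {
      scoreMatrix(epochFeatures(record, ch))
    })
    names(out) <- names(SummarizedExperiment::assays(record))
    out
  } else {
    scoreMatrix(as.matrix(record))
  }
}

#' Serialize a discriminative model (with calibration and standardization)
#' @param model a \linkS4class{DiscriminativeModel}.
#' @param path output path (RDS container).
#' @return \code{path}, invisibly.
#' @export
writeDiscriminative <- function(model, path) {
  saveRDS(list(format = "seizAdapt-svm", version = "1", model = model),
          path)
  invisible(path)
}

#' Read a discriminative model written by \code{\link{writeDiscriminative}}
#' @param path input path.
#' @return a \linkS4class{DiscriminativeModel}.
#' @export
readDiscriminative <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "seizAdapt-svm")) {
    stop("not a seizAdapt discriminative-model container: ", path)
  }
  obj$model
}
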
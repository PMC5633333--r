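#' @rdname FeatureRecord-class
#' @param x,object a FeatureRecord (or other seizAdapt object, per method).
#' @export
setGeneric("patientID", function(x) standardGeneric("patientID"))

#' @rdname FeatureRecord-class
#' @export
setMethod("patientID", "FeatureRecord", function(x) x@patientID)

#' @rdname FeatureRecord-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname FeatureRecord-class
#' @export
setMethod("nEpochs", "FeatureRecord", function(x) ncol(x))

#' @rdname FeatureRecord-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname FeatureRecord-class
#' @export
setMethod("nChannels", "FeatureRecord",
          function(x) length(SummarizedExperiment::assays(x)))

#' @rdname FeatureRecord-class
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' @rdname FeatureRecord-class
#' @export
setMethod("featureDim", "FeatureRecord", function(x) nrow(x))

#' @rdname FeatureRecord-class
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' @rdname FeatureRecord-class
#' @export
setMethod("epochLabels", "FeatureRecord",
          function(x) SummarizedExperiment::colData(x)$label)

#' @rdname FeatureRecord-class
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname FeatureRecord-class
#' @export
setMethod("epochTimes", "FeatureRecord",
          function(x) SummarizedExperiment::colData(x)$t_start)

#' @rdname FeatureRecord-class
#' @export
setGeneric("epochHop", function(x) standardGeneric("epochHop"))

#' @rdname FeatureRecord-class
#' @export
setMethod("epochHop", "FeatureRecord", function(x) x@epochHop)

#' @rdname FeatureRecord-class
#' @export
setGeneric("epochDuration", function(x) standardGeneric("epochDuration"))

#' @rdname FeatureRecord-class
#' @export
setMethod("epochDuration", "FeatureRecord", function(x) x@epochDuration)

#' Per-channel epoch feature matrix
#'
#' Returns the epochs x features matrix of one channel.
#'
#' @param x a \linkS4class{FeatureRecord}.
#' @param channel channel index or name.
#' @return numeric matrix, epochs x features.
#' @export
epochFeatures <- function(x, channel = 1L) {
  t(SummarizedExperiment::assays(x)[[channel]])
}

#' Record duration in hours
#' @param x a \linkS4class{FeatureRecord}.
#' @return hours spanned by the record (last epoch end).
#' @export
recordHours <- function(x) {
  (epochTimes(x)[nEpochs(x)] + epochDuration(x)) / 3600
}

#' Generating truth of a synthetic record
#'
#' For records produced by \code{\link{generateCohort}}: the patient-level
#' generating parameters (shifted class mixtures, shift vectors, events).
#' NULL for records loaded from disk.
#'
#' @param x a \linkS4class{FeatureRecord}.
#' @return list or NULL.
#' @export
recordTruth <- function(x) S4Vectors::metadata(x)$truth

setMethod("show", "FeatureRecord", function(object) {
  cat("FeatureRecord '", object@patientID, "': ",
      nEpochs(object), " epochs x ", featureDim(object), " features x ",
      nChannels(object), " channels\n", sep = "")
  cat("  epoch ", object@epochDuration, " s, hop ", object@epochHop,
      " s, span ", sprintf("%.2f", recordHours(object)), " h, ",
      sum(epochLabels(object)), " seizure epochs (",
      sprintf("%.1f%%", 100 * mean(epochLabels(object))), ")\n", sep = "")
})

#' @rdname ClassGMM-class
#' @param x,object a ClassGMM.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname ClassGMM-class
#' @export
setMethod("nComponents", "ClassGMM", function(x) nrow(x@means))

#' @rdname ClassGMM-class
#' @export
setGeneric("classTag", function(x) standardGeneric("classTag"))

#' @rdname ClassGMM-class
#' @export
setMethod("classTag", "ClassGMM", function(x) x@classTag)

#' @rdname ClassGMM-class
#' @export
setGeneric("gmmMeans", function(x) standardGeneric("gmmMeans"))

#' @rdname ClassGMM-class
#' @export
setMethod("gmmMeans", "ClassGMM", function(x) x@means)

#' @rdname ClassGMM-class
#' @export
setGeneric("gmmWeights", function(x) standardGeneric("gmmWeights"))

#' @rdname ClassGMM-class
#' @export
setMethod("gmmWeights", "ClassGMM", function(x) x@weights)

#' @rdname ClassGMM-class
#' @export
setGeneric("gmmVariances", function(x) standardGeneric("gmmVariances"))

#' @rdname ClassGMM-class
#' @export
setMethod("gmmVariances", "ClassGMM", function(x) x@variances)

setMethod("show", "ClassGMM", function(object) {
  cat("ClassGMM [", object@classTag, "]: ", nComponents(object),
      " diagonal components in ", ncol(object@means), " dimensions\n",
      sep = "")
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
      "\n")
})

#' @rdname ProbabilitySeries-class
#' @param x,object a ProbabilitySeries.
#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))

#' @rdname ProbabilitySeries-class
#' @export
setMethod("probValues", "ProbabilitySeries", function(x) x@values)

#' @rdname ProbabilitySeries-class
#' @export
setGeneric("sourceTag", function(x) standardGeneric("sourceTag"))

#' @rdname ProbabilitySeries-class
#' @export
setMethod("sourceTag", "ProbabilitySeries", function(x) x@sourceTag)

setMethod("length", "ProbabilitySeries", function(x) length(x@values))

setMethod("show", "ProbabilitySeries", function(object) {
  cat("ProbabilitySeries [", object@sourceTag, "]: ", length(object@values),
      " epochs, mean ", sprintf("%.4f", mean(object@values)), "\n", sep = "")
})

setMethod("show", "ClusterPartition", function(object) {
  cat("ClusterPartition: K =", object@K, "equal-width bins on [0,1]\n")
})

#' @rdname WeightSchedule-class
#' @param x,object a WeightSchedule.
#' @export
setGeneric("scheduleAlpha", function(x) standardGeneric("scheduleAlpha"))

#' @rdname WeightSchedule-class
#' @export
setMethod("scheduleAlpha", "WeightSchedule", function(x) x@alpha)

#' @rdname WeightSchedule-class
#' @export
setGeneric("scheduleBeta", function(x) standardGeneric("scheduleBeta"))

#' @rdname WeightSchedule-class
#' @export
setMethod("scheduleBeta", "WeightSchedule", function(x) x@beta)

setMethod("show", "WeightSchedule", function(object) {
  cat("WeightSchedule [", object@kind, "]: K = ", length(object@beta),
      ", alpha = ", sprintf("%.4f", object@alpha), "\n", sep = "")
  cat("  beta:", paste(sprintf("%.4f", object@beta), collapse = " "), "\n")
})
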
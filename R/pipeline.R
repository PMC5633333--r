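#' Experiment configuration for the detection pipeline
#'
#' Bundles every tunable of the leave-one-patient-out protocol: detector
#' variant, hourly adaptation window, confidence-clustering parameters,
#' fusion and post-processing settings.
#'
#' @param mode "PI" (patient-independent), "PA" (patient-adaptive,
#'   automatic labels) or "ORACLE" (patient-dependent: retrained with a
#'   true-labelled prefix of the test record).
#' @param adaptWindowHours adaptation window in hours (default 1).
#' @param K number of confidence clusters (default 10).
#' @param scheduleKind weight schedule (default "exp2").
#' @param scheduleParams shape parameters for the schedule.
#' @param hbar original-data mass of the schedule (default sum(h), i.e.
#'   alpha = 0.5; Inf disables adaptation, alpha = 1).
#' @param nIter MAP passes per adaptation step (default 3).
#' @param fusion fuse the generative branch with the discriminative one
#'   (geometric mean) when scoring (default TRUE).
#' @param smoothWindow temporal smoothing window in epochs (odd,
#'   default 3).
#' @param threshold decision threshold for event extraction (default 0.5).
#' @param minEventDurationS minimum detection duration (default 8 s).
#' @param oraclePrefixMinutes true-labelled prefix used by ORACLE mode
#'   (default 10).
#' @param priorS seizure prior of the generative posterior (default 0.5).
#' @param gmmComponents mixture components per class model (default 8).
#' @param gmmMaxRows per-class cap on EM training rows (default 8000).
#' @param svm discriminative-branch settings forwarded to
#'   \code{\link{fitDiscriminative}}.
#' @param seed base seed; per-fold seeds are derived from it.
#' @return a validated list with class "ExperimentConfig".
#' @export
experimentConfig <- function(mode = c("PI", "PA", "ORACLE"),
                             adaptWindowHours = 1,
                             K = 10L,
                             scheduleKind = "exp2",
                             scheduleParams = list(),
                             hbar = NULL,
                             nIter = 3L,
                             fusion = TRUE,
                             smoothWindow = 3L,
                             threshold = 0.5,
                             minEventDurationS = 8,
                             oraclePrefixMinutes = 10,
                             priorS = 0.5,
                             gmmComponents = 8L,
                             gmmMaxRows = 8000L,
                             svm = list(),
                             seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, adaptWindowHours = adaptWindowHours,
              K = as.integer(K), scheduleKind = scheduleKind,
              scheduleParams = scheduleParams, hbar = hbar,
              nIter = as.integer(nIter), fusion = fusion,
              smoothWindow = as.integer(smoothWindow),
              threshold = threshold,
              minEventDurationS = minEventDurationS,
              oraclePrefixMinutes = oraclePrefixMinutes,
              priorS = priorS, gmmComponents = as.integer(gmmComponents),
              gmmMaxRows = as.integer(gmmMaxRows), svm = svm,
              seed = as.integer(seed))
  stopifnot(cfg$adaptWindowHours > 0, cfg$K >= 1L, cfg$nIter >= 1L,
            cfg$threshold > 0, cfg$threshold < 1,
            cfg$priorS > 0, cfg$priorS < 1, cfg$gmmComponents >= 1L)
  class(cfg) <- "ExperimentConfig"
  cfg
}

# pool per-epoch features and labels over records and channels
pooledEpochs <- function(records) {
  Xs <- list(); ys <- list()
  j <- 0L
  for (rec in records) {
    labs <- epochLabels(rec)
    for (ch in seq_len(nChannels(rec))) {
      j <- j + 1L
      Xs[[j]] <- epochFeatures(rec, ch)
      ys[[j]] <- labs
    }
  }
  list(X = do.call(rbind, Xs), labels = unlist(ys))
}

#' Train the patient-independent models
#'
#' Pools the per-epoch features of the training records over patients and
#' channels, trains the calibrated discriminative classifier, and fits one
#' diagonal-covariance mixture per class by EM (class-conditionally, with
#' an optional per-class row cap for the EM).
#'
#' @param records list of training \linkS4class{FeatureRecord}s.
#' @param config an \code{\link{experimentConfig}}.
#' @param seed integer seed.
#' @return list with \code{svm} (\linkS4class{DiscriminativeModel}),
#'   \code{gmmS}, \code{gmmNS} (\linkS4class{ClassGMM}) and \code{priorS}.
#' @export
trainPIModels <- function(records, config = experimentConfig(), seed = 1L) {
  pool <- pooledEpochs(records)
  if (length(unique(pool$labels)) < 2L) {
    stop("training records must contain both classes")
  }
  svmModel <- fitDiscriminative(pool$X, pool$labels, config$svm, seed)
  capRows <- function(X, cap, s) {
    if (nrow(X) <= cap) return(X)
    withSeed(s, X[sample.int(nrow(X), cap), , drop = FALSE])
  }
  XS <- capRows(pool$X[pool$labels == 1, , drop = FALSE],
                config$gmmMaxRows, seed + 101L)
  XNS <- capRows(pool$X[pool$labels == 0, , drop = FALSE],
                 config$gmmMaxRows, seed + 102L)
  gmmS <- fitGMM(XS, min(config$gmmComponents, nrow(XS)),
                 classTag = "S", seed = seed + 1L)
  gmmNS <- fitGMM(XNS, min(config$gmmComponents, nrow(XNS)),
                  classTag = "NS", seed = seed + 2L)
  list(svm = svmModel, gmmS = gmmS, gmmNS = gmmNS, priorS = config$priorS)
}

#' Score a record with a trained system
#'
#' Per channel: calibrated discriminative probabilities, generative
#' posterior, geometric-mean fusion (per \code{branch}), temporal
#' smoothing; channels are then aggregated by the element-wise maximum.
#'
#' @param models output of \code{\link{trainPIModels}}.
#' @param record a \linkS4class{FeatureRecord}.
#' @param config an \code{\link{experimentConfig}}.
#' @param branch "FUSION" (default), "SVM" or "GMM".
#' @param gmmS,gmmNS optional adapted class models overriding the trained
#'   ones.
#' @param pSvmCh optional precomputed per-channel discriminative series.
#' @return an aggregated \linkS4class{ProbabilitySeries}.
#' @export
scoreRecord <- function(models, record, config = experimentConfig(),
                        branch = c("FUSION", "SVM", "GMM"),
                        gmmS = models$gmmS, gmmNS = models$gmmNS,
                        pSvmCh = NULL) {
  branch <- match.arg(branch)
  if (!config$fusion && branch == "FUSION") branch <- "SVM"
  if (is.null(pSvmCh)) pSvmCh <- predictProba(models$svm, record)
  per <- lapply(seq_len(nChannels(record)), function(ch) {
    out <- if (branch == "SVM") {
      pSvmCh[[ch]]
    } else {
      pg <- ProbabilitySeries(
        clampProbs(gmmPosterior(epochFeatures(record, ch), gmmS, gmmNS,
                                models$priorS)), "GMM")
      if (branch == "GMM") pg else geometricMeanFusion(pg, pSvmCh[[ch]])
    }
    smoothProbabilities(out, config$smoothWindow)
  })
  aggregateChannels(per)
}

# epoch/event metrics of a scored record
evalSeries <- function(series, record, config) {
  labs <- epochLabels(record)
  v <- probValues(series)
  det <- thresholdToEvents(series, config$threshold, epochHop(record),
                           config$minEventDurationS)
  ann <- labelsToEvents(labs, epochHop(record))
  em <- eventMetrics(det, ann, recordHours(record))
  data.frame(patient = patientID(record),
             auc = aucScore(v, labs), auc90 = auc90(v, labs),
             gdr = em$gdr, fdPerHour = em$fdPerHour,
             nTrueEvents = em$nTrueEvents, nFalse = em$nFalse)
}

#' Streaming hourly adaptation of one test record
#'
#' Starting from the patient-independent class models, the record is
#' consumed in windows of \code{adaptWindowHours}; after each window the
#' confidence-weighted MAP update is applied to both class models using
#' that window's pooled channel features and their raw discriminative
#' probabilities, and the fused system re-scores the \emph{entire} record
#' retrospectively. Point 0 of the returned curve is the unadapted
#' (PI-FUSION) performance; a record shorter than one window is adapted in
#' a single step.
#'
#' @param record the test \linkS4class{FeatureRecord}.
#' @param models patient-independent models from
#'   \code{\link{trainPIModels}}.
#' @param config an \code{\link{experimentConfig}}.
#' @return list: \code{curve} (data.frame hoursAdapted, auc, auc90),
#'   adapted \code{gmmS}, \code{gmmNS}, and \code{series} (final fused,
#'   aggregated \linkS4class{ProbabilitySeries}).
#' @export
hourlyAdaptationRun <- function(record, models,
                                config = experimentConfig(mode = "PA")) {
  pSvmCh <- predictProba(models$svm, record)
  partition <- partitionProbabilitySpace(config$K)
  schedule <- sampleWeightSchedule(config$scheduleKind, config$K,
                                   config$scheduleParams, config$hbar)
  labs <- epochLabels(record)
  gmmS <- models$gmmS; gmmNS <- models$gmmNS
  evalPoint <- function(gS, gNS) {
    s <- scoreRecord(models, record, config, "FUSION", gS, gNS, pSvmCh)
    c(aucScore(probValues(s), labs), auc90(probValues(s), labs))
  }
  m <- evalPoint(gmmS, gmmNS)
  curve <- data.frame(hoursAdapted = 0, auc = m[1], auc90 = m[2])
  windowS <- config$adaptWindowHours * 3600
  t <- epochTimes(record)
  nW <- max(1L, ceiling((t[length(t)] + epochDuration(record)) / windowS))
  for (w in seq_len(nW)) {
    idx <- which(t >= (w - 1) * windowS & t < w * windowS)
    if (!length(idx)) next
    X <- do.call(rbind, lapply(seq_len(nChannels(record)), function(ch) {
      epochFeatures(record, ch)[idx, , drop = FALSE]
    }))
    p <- unlist(lapply(seq_len(nChannels(record)), function(ch) {
      probValues(pSvmCh[[ch]])[idx]
    }))
    ad <- confidenceWeightedMapUpdate(gmmS, gmmNS, X, p, schedule,
                                      partition, config$nIter)
    gmmS <- ad$gmmS; gmmNS <- ad$gmmNS
    m <- evalPoint(gmmS, gmmNS)
    curve <- rbind(curve,
                   data.frame(hoursAdapted = w * config$adaptWindowHours,
                              auc = m[1], auc90 = m[2]))
  }
  list(curve = curve, gmmS = gmmS, gmmNS = gmmNS,
       series = scoreRecord(models, record, config, "FUSION", gmmS, gmmNS,
                            pSvmCh))
}

#' Oracle (patient-dependent) evaluation of one test record
#'
#' Retrains the full system with the true-labelled prefix of the test
#' record mixed into the other patients' training data, then evaluates on
#' the remaining unseen portion of the record. A zero-length prefix
#' reduces exactly to the patient-independent system.
#'
#' @param record the test \linkS4class{FeatureRecord}.
#' @param trainRecords the other patients' records.
#' @param config an \code{\link{experimentConfig}} (uses
#'   \code{oraclePrefixMinutes}).
#' @param seed integer seed.
#' @return list: \code{report} (one-row data.frame of metrics on the
#'   unseen remainder), \code{models}.
#' @export
runOracle <- function(record, trainRecords,
                      config = experimentConfig(mode = "ORACLE"),
                      seed = 1L) {
  t <- epochTimes(record)
  prefixS <- config$oraclePrefixMinutes * 60
  nPrefix <- sum(t < prefixS)
  if (nPrefix >= nEpochs(record)) {
    stop("oracle prefix covers the whole record")
  }
  trainSet <- trainRecords
  if (nPrefix > 0L) {
    trainSet <- c(trainRecords, list(subsetEpochs(record, seq_len(nPrefix))))
  }
  models <- trainPIModels(trainSet, config, seed)
  rest <- subsetEpochs(record, (nPrefix + 1L):nEpochs(record))
  series <- scoreRecord(models, rest, config)
  list(report = evalSeries(series, rest, config), models = models)
}

#' Leave-one-patient-out evaluation of a cohort
#'
#' For every held-out patient the patient-independent models are trained
#' on the remaining patients (plus optional background-only records) and
#' the configured detector variant is run on the held-out record: PI
#' scores directly, PA performs streaming hourly adaptation with
#' retrospective re-scoring, ORACLE retrains with a true-labelled prefix
#' and evaluates the remainder. Fully deterministic given
#' \code{config$seed}.
#'
#' @param cohort list of at least two \linkS4class{FeatureRecord}s.
#' @param config an \code{\link{experimentConfig}}.
#' @param backgroundRecords optional list of extra seizure-free records
#'   added to every fold's training set (mirroring the augmentation of a
#'   training corpus with background-only patients).
#' @return list: \code{perPatient} (data.frame of per-patient metrics),
#'   \code{summary} (named means), \code{curves} (per-patient adaptation
#'   curves, PA mode only), \code{series} (final scored
#'   \linkS4class{ProbabilitySeries} per patient, PI/PA modes),
#'   \code{mode}.
#' @export
runLoo <- function(cohort, config = experimentConfig(),
                   backgroundRecords = list()) {
  if (length(cohort) < 2L) stop("leave-one-out needs at least 2 patients")
  rows <- list(); curves <- list(); seriesList <- list()
  for (i in seq_along(cohort)) {
    test <- cohort[[i]]
    train <- c(cohort[-i], backgroundRecords)
    foldSeed <- config$seed + 1000L * i
    if (config$mode == "ORACLE") {
      rows[[i]] <- runOracle(test, train, config, foldSeed)$report
    } else {
      models <- trainPIModels(train, config, foldSeed)
      if (config$mode == "PI") {
        series <- scoreRecord(models, test, config)
        rows[[i]] <- evalSeries(series, test, config)
        seriesList[[patientID(test)]] <- series
      } else {
        run <- hourlyAdaptationRun(test, models, config)
        rows[[i]] <- evalSeries(run$series, test, config)
        curves[[patientID(test)]] <- run$curve
        seriesList[[patientID(test)]] <- run$series
      }
    }
  }
  perPatient <- do.call(rbind, rows)
  num <- c("auc", "auc90", "gdr", "fdPerHour")
  list(perPatient = perPatient,
       summary = colMeans(perPatient[num], na.rm = TRUE),
       curves = curves, series = seriesList, mode = config$mode)
}
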
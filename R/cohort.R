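#' Configuration of a synthetic neonatal cohort
#'
#' Describes the statistical structure of a simulated cohort of long
#' multichannel EEG feature streams: rare seizure events of variable
#' duration placed by a Poisson process inside hours of non-seizure
#' background, class-conditional diagonal Gaussian mixtures for the
#' features, and a per-patient additive shift of the component means that
#' the adaptation stage is meant to capture.
#'
#' Defaults encode the cohort the package's experiments run on: 6 patients,
#' 4 h each, seizure rate 1.7 events/h (the clinical rate of roughly 1389
#' seizures over 817 h), durations 60-240 s, 16 features on 2 independent
#' channels, 3 population components per class with class separation 0.7 on
#' 8 of the 16 dimensions, and patient shift scale 0.4.
#'
#' @param nPatients number of patients.
#' @param hoursPerPatient record length per patient (hours).
#' @param seizureRatePerHour Poisson rate of seizure events.
#' @param seizureDurationS (min, max) seizure duration in seconds.
#' @param D feature dimension.
#' @param nChannels number of independent channels.
#' @param epochDurationS,epochHopS epoch geometry (seconds).
#' @param populationParams list: \code{nComponents} per class,
#'   \code{sepScale} and \code{sepDims} (mean separation of the seizure
#'   class on the first sepDims dimensions), \code{meanScatter} (sd of the
#'   shared background component means), \code{jitterScatter} (sd of the
#'   per-component jitter of the seizure means around the shifted
#'   background layout), \code{varRange} (uniform range of component
#'   variances).
#' @param patientShiftScale sd of the additive per-patient Gaussian shift
#'   applied to all component means of a class (one draw per class,
#'   shared across the patient's whole record).
#' @param seed integer RNG seed.
#' @return a validated list with class "CohortConfig".
#' @export
cohortConfig <- function(nPatients = 6L,
                         hoursPerPatient = 4,
                         seizureRatePerHour = 1.7,
                         seizureDurationS = c(60, 240),
                         D = 16L,
                         nChannels = 2L,
                         epochDurationS = 8,
                         epochHopS = 4,
                         populationParams = list(),
                         patientShiftScale = 0.4,
                         seed = 1L) {
  pp <- modifyList(list(nComponents = 3L, sepScale = 0.7,
                        sepDims = min(8L, as.integer(D)),
                        meanScatter = 0.75, jitterScatter = 0.2,
                        varRange = c(0.6, 1.4)),
                   populationParams)
  cfg <- list(nPatients = as.integer(nPatients),
              hoursPerPatient = hoursPerPatient,
              seizureRatePerHour = seizureRatePerHour,
              seizureDurationS = seizureDurationS,
              D = as.integer(D), nChannels = as.integer(nChannels),
              epochDurationS = epochDurationS, epochHopS = epochHopS,
              populationParams = pp,
              patientShiftScale = patientShiftScale,
              seed = as.integer(seed))
  stopifnot(cfg$nPatients >= 1L, cfg$hoursPerPatient > 0,
            cfg$seizureRatePerHour >= 0,
            length(cfg$seizureDurationS) == 2L,
            cfg$seizureDurationS[1] > 0,
            cfg$seizureDurationS[1] <= cfg$seizureDurationS[2],
            cfg$D >= 1L, cfg$nChannels >= 1L,
            cfg$epochDurationS > 0, cfg$epochHopS > 0,
            pp$nComponents >= 1L, pp$sepDims <= cfg$D,
            cfg$patientShiftScale >= 0)
  class(cfg) <- "CohortConfig"
  cfg
}

# draw the population class-conditional mixtures: the non-seizure mixture
# sets the shared background structure; the seizure mixture reuses its
# component layout shifted by sepScale on the first sepDims dimensions
# (plus a small per-component jitter), so class overlap is governed by
# sepScale rather than by independent component placement
drawPopulationPair <- function(cfg) {
  pp <- cfg$populationParams
  M <- pp$nComponents; D <- cfg$D
  meansNS <- matrix(rnorm(M * D, sd = pp$meanScatter), M, D)
  varsNS <- matrix(runif(M * D, pp$varRange[1], pp$varRange[2]), M, D)
  wNS <- runif(M, 0.5, 1.5)
  sep <- c(rep(pp$sepScale, pp$sepDims), rep(0, D - pp$sepDims))
  jitter <- matrix(rnorm(M * D, sd = pp$jitterScatter), M, D)
  meansS <- meansNS + matrix(sep, M, D, byrow = TRUE) + jitter
  varsS <- matrix(runif(M * D, pp$varRange[1], pp$varRange[2]), M, D)
  wS <- runif(M, 0.5, 1.5)
  list(S = ClassGMM(meansS, wS / sum(wS), varsS, classTag = "S"),
       NS = ClassGMM(meansNS, wNS / sum(wNS), varsNS, classTag = "NS"))
}

# place non-overlapping seizure events by a Poisson process
placeEvents <- function(totalS, ratePerHour, durRange) {
  n <- rpois(1L, ratePerHour * totalS / 3600)
  if (n == 0L) return(data.frame(onset = numeric(0), offset = numeric(0)))
  onsets <- numeric(0); offsets <- numeric(0)
  attempts <- 0L
  for (j in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 200L * n) {
        stop("seizure rate too high: events cannot be placed without overlap")
      }
      dur <- runif(1L, durRange[1], durRange[2])
      if (dur >= totalS) {
        stop("seizure duration exceeds record length")
      }
      on <- runif(1L, 0, totalS - dur)
      off <- on + dur
      if (!any(on < offsets & off > onsets)) break
    }
    onsets <- c(onsets, on); offsets <- c(offsets, off)
  }
  o <- order(onsets)
  data.frame(onset = onsets[o], offset = offsets[o])
}

# shift all component means of a mixture by one vector
shiftGMM <- function(gmm, shift) {
  gmm@means <- sweep(gmm@means, 2L, shift, "+")
  gmm
}

#' Generate a synthetic cohort of feature records
#'
#' Draws one population pair of class-conditional mixtures, then one
#' patient-specific shifted pair per patient; places seizure events by a
#' Poisson process and draws epoch features class-conditionally and
#' independently per channel. The true generating parameters of every
#' patient are retained in the record metadata for parameter-recovery
#' experiments. Fully reproducible from \code{config$seed}.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list of \linkS4class{FeatureRecord}, one per patient.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  withSeed(config$seed, {
    pop <- drawPopulationPair(config)
    lapply(seq_len(config$nPatients), function(p) {
      generatePatient(config, pop$S, pop$NS, p)
    })
  })
}

generatePatient <- function(config, popS, popNS, p) {
  totalS <- config$hoursPerPatient * 3600
  hop <- config$epochHopS; dur <- config$epochDurationS
  if (totalS < dur) stop("record shorter than one epoch")
  N <- floor((totalS - dur) / hop) + 1L
  shiftS <- rnorm(config$D, sd = config$patientShiftScale)
  shiftNS <- rnorm(config$D, sd = config$patientShiftScale)
  gmmS <- shiftGMM(popS, shiftS)
  gmmNS <- shiftGMM(popNS, shiftNS)
  events <- placeEvents(totalS, config$seizureRatePerHour,
                        config$seizureDurationS)
  tStart <- (seq_len(N) - 1L) * hop
  centres <- tStart + dur / 2
  labels <- rep(0, N)
  for (e in seq_len(nrow(events))) {
    labels[centres >= events$onset[e] & centres < events$offset[e]] <- 1
  }
  nS <- sum(labels == 1)
  features <- lapply(seq_len(config$nChannels), function(ch) {
    X <- matrix(0, N, config$D)
    if (nS > 0) X[labels == 1, ] <- sampleGMM(gmmS, nS)
    X[labels == 0, ] <- sampleGMM(gmmNS, N - nS)
    X
  })
  names(features) <- paste0("ch", seq_len(config$nChannels))
  FeatureRecord(features, labels, tStart,
                patientID = sprintf("P%02d", p),
                epochDuration = dur, epochHop = hop,
                truth = list(gmmS = gmmS, gmmNS = gmmNS,
                             shiftS = shiftS, shiftNS = shiftNS,
                             populationS = popS, populationNS = popNS,
                             events = events))
}
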
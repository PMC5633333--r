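#' Geometric-mean fusion of two probability streams
#'
#' Element-wise sqrt(P_GMM * P_SVM); the geometric mean suits fusing
#' classifiers whose outputs follow different probability distributions.
#'
#' @param pGmm,pSvm \linkS4class{ProbabilitySeries} or numeric vectors of
#'   equal length with values in [0,1].
#' @return a \linkS4class{ProbabilitySeries} tagged "FUSION".
#' @export
geometricMeanFusion <- function(pGmm, pSvm) {
  a <- if (is(pGmm, "ProbabilitySeries")) probValues(pGmm) else pGmm
  b <- if (is(pSvm, "ProbabilitySeries")) probValues(pSvm) else pSvm
  if (length(a) != length(b)) stop("series lengths differ")
  stopifnot(all(a >= 0 & a <= 1), all(b >= 0 & b <= 1))
  ProbabilitySeries(sqrt(a * b), "FUSION")
}

#' Temporal smoothing of a probability series
#'
#' Centred moving average with an odd window; at the edges the window
#' shrinks symmetrically to what fits.
#'
#' @param series \linkS4class{ProbabilitySeries} or numeric vector.
#' @param windowEpochs odd window length in epochs (1 = identity).
#' @return smoothed series of the same type/tag.
#' @export
smoothProbabilities <- function(series, windowEpochs = 3L) {
  isPS <- is(series, "ProbabilitySeries")
  v <- if (isPS) probValues(series) else series
  w <- as.integer(windowEpochs)
  if (w < 1L || w %% 2L == 0L) stop("window must be odd and >= 1")
  if (w > 1L) {
    n <- length(v)
    half <- (w - 1L) %/% 2L
    cs <- cumsum(c(0, v))
    i <- seq_len(n)
    lo <- pmax(i - half, 1L)
    hi <- pmin(i + half, n)
    v <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  if (isPS) ProbabilitySeries(v, sourceTag(series)) else v
}

#' Aggregate per-channel probabilities across channels
#'
#' Element-wise maximum: seizure activity on any single channel flags the
#' epoch.
#'
#' @param perChannel non-empty list of \linkS4class{ProbabilitySeries} (or
#'   numeric vectors) of equal length.
#' @return a single series of the common type.
#' @export
aggregateChannels <- function(perChannel) {
  if (!length(perChannel)) stop("empty channel list")
  vals <- lapply(perChannel, function(s) {
    if (is(s, "ProbabilitySeries")) probValues(s) else s
  })
  n <- unique(lengths(vals))
  if (length(n) != 1L) stop("channel series lengths differ")
  out <- do.call(pmax, vals)
  if (is(perChannel[[1]], "ProbabilitySeries")) {
    ProbabilitySeries(out, sourceTag(perChannel[[1]]))
  } else out
}

#' Threshold a probability series into detection events
#'
#' Maximal runs of epochs with probability >= threshold become detection
#' events; events shorter than \code{minDurationS} are discarded. The run
#' spanning epochs f..l maps to ((f-1)*hop, l*hop) seconds.
#'
#' @param series \linkS4class{ProbabilitySeries} or numeric vector.
#' @param threshold decision threshold in (0,1).
#' @param epochHopS hop between epoch starts (s).
#' @param minDurationS minimum event duration in seconds (default 8, one
#'   epoch).
#' @return data.frame with columns onset, offset, peak (peak probability
#'   within the event).
#' @export
thresholdToEvents <- function(series, threshold = 0.5, epochHopS = 4,
                              minDurationS = 8) {
  stopifnot(threshold > 0, threshold < 1)
  v <- if (is(series, "ProbabilitySeries")) probValues(series) else series
  hit <- as.numeric(v >= threshold)
  ev <- labelsToEvents(hit, epochHopS)
  if (!nrow(ev)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      peak = numeric(0)))
  }
  ev$peak <- vapply(seq_len(nrow(ev)), function(e) {
    f <- ev$onset[e] / epochHopS + 1L
    l <- ev$offset[e] / epochHopS
    max(v[f:l])
  }, numeric(1))
  ev[ev$offset - ev$onset >= minDurationS, , drop = FALSE]
}
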
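#' Epoch-based area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted half; identical to the
#' trapezoidal area under the empirical sensitivity/specificity curve.
#'
#' @param probs numeric scores (higher = more seizure-like).
#' @param labels binary 0/1 vector aligned to probs.
#' @return AUC in [0,1].
#' @export
aucScore <- function(probs, labels) {
  checkTwoClasses(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

checkTwoClasses <- function(labels) {
  stopifnot(all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in labels")
  }
}

#' Empirical ROC curve
#'
#' Sensitivity/specificity pairs at every distinct threshold (plus the two
#' trivial endpoints). Tied scores produce diagonal segments, so the
#' trapezoidal area equals the rank-based AUC.
#'
#' @param probs numeric scores.
#' @param labels binary 0/1 vector.
#' @return data.frame with columns threshold, sensitivity, specificity,
#'   ordered from the strictest threshold (sens 0, spec 1) downwards.
#' @export
rocCurve <- function(probs, labels) {
  checkTwoClasses(labels)
  o <- order(probs, decreasing = TRUE)
  p <- probs[o]; y <- labels[o]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- !duplicated(p, fromLast = TRUE) # last index of each tied block
  data.frame(threshold = c(Inf, p[last]),
             sensitivity = c(0, tp[last] / n1),
             specificity = c(1, 1 - fp[last] / n0))
}

#' Partial AUC restricted to specificity above 90%
#'
#' Trapezoidal area of the ROC curve over specificity in [0.9, 1], with
#' linear interpolation at specificity 0.9, normalised by the maximum
#' attainable area 0.1 so that perfect discrimination scores 1 and a
#' chance-level continuous classifier scores 0.05.
#'
#' @param probs numeric scores.
#' @param labels binary 0/1 vector.
#' @param specMin lower specificity limit (default 0.9).
#' @return normalised partial AUC in [0,1].
#' @export
auc90 <- function(probs, labels, specMin = 0.9) {
  curve <- rocCurve(probs, labels)
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  fprMax <- 1 - specMin
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  # clip the polyline at fpr = fprMax with linear interpolation
  keep <- fpr < fprMax
  fx <- fpr[keep]; fy <- tpr[keep]
  j <- which(!keep)[1]
  if (!is.na(j)) {
    if (fpr[j] > fprMax && j > 1L && fpr[j] > fpr[j - 1L]) {
      t <- (fprMax - fpr[j - 1L]) / (fpr[j] - fpr[j - 1L])
      yCut <- tpr[j - 1L] + t * (tpr[j] - tpr[j - 1L])
    } else {
      yCut <- tpr[j]
    }
    fx <- c(fx, fprMax); fy <- c(fy, yCut)
  }
  area <- sum(diff(fx) * (head(fy, -1) + tail(fy, -1)) / 2)
  area / fprMax
}

#' Correlated-ROC significance test for paired AUCs
#'
#' z-test for the difference of two AUCs measured on the same epochs,
#' accounting for the correlation of the two ROC areas. Variances and the
#' covariance are estimated from the per-observation placement values of
#' the paired scores; z = (AUC_A - AUC_B) / SE_diff with a two-sided
#' normal p-value.
#'
#' @param probsA,probsB aligned score vectors of the two systems.
#' @param labels binary 0/1 vector.
#' @return list with \code{z}, \code{p}, \code{aucA}, \code{aucB}.
#'   Identical series give z = 0, p = 1.
#' @export
compareAucCorrelated <- function(probsA, probsB, labels) {
  checkTwoClasses(labels)
  stopifnot(length(probsA) == length(probsB),
            length(probsA) == length(labels))
  pos <- labels == 1; neg <- labels == 0
  placement <- function(s) {
    x <- s[pos]; y <- s[neg]
    cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
    list(v10 = rowMeans(cmp), v01 = colMeans(cmp))
  }
  pa <- placement(probsA)
  pb <- placement(probsB)
  aucA <- mean(pa$v10)
  aucB <- mean(pb$v10)
  n1 <- sum(pos); n0 <- sum(neg)
  var1 <- function(x) if (length(x) < 2L) 0 else var(x)
  cov1 <- function(x, y) if (length(x) < 2L) 0 else cov(x, y)
  vA <- var1(pa$v10) / n1 + var1(pa$v01) / n0
  vB <- var1(pb$v10) / n1 + var1(pb$v01) / n0
  cAB <- cov1(pa$v10, pb$v10) / n1 + cov1(pa$v01, pb$v01) / n0
  se <- sqrt(max(vA + vB - 2 * cAB, 0))
  diff <- aucA - aucB
  z <- if (se == 0 || diff == 0) 0 else diff / se
  list(z = z, p = if (z == 0) 1 else 2 * pnorm(-abs(z)),
       aucA = aucA, aucB = aucB)
}

#' Event-based detection metrics (GDR and FD/h)
#'
#' An annotated seizure event counts as detected iff at least one
#' detection overlaps it by at least \code{minOverlapS} seconds (multiple
#' detections of the same event are not double-counted); a detection that
#' overlaps no annotated event is one false detection.
#'
#' @param detections data.frame with onset, offset columns (seconds).
#' @param annotation data.frame with onset, offset columns (seconds).
#' @param recordHours record duration in hours (> 0).
#' @param minOverlapS minimum overlap to count a detection (default 1 s).
#' @return list with \code{gdr}, \code{fdPerHour}, \code{nTrueEvents},
#'   \code{nDetected}, \code{nFalse}.
#' @export
eventMetrics <- function(detections, annotation, recordHours,
                         minOverlapS = 1) {
  stopifnot(recordHours > 0)
  nT <- nrow(annotation)
  nD <- nrow(detections)
  overlap <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))
  detected <- logical(nT)
  falseDet <- rep(TRUE, nD)
  for (e in seq_len(nT)) {
    ov <- overlap(annotation$onset[e], annotation$offset[e],
                  detections$onset, detections$offset)
    detected[e] <- any(ov >= minOverlapS)
    falseDet[ov > 0] <- FALSE
  }
  list(gdr = if (nT > 0) mean(detected) else NA_real_,
       fdPerHour = sum(falseDet) / recordHours,
       nTrueEvents = nT, nDetected = sum(detected),
       nFalse = sum(falseDet))
}

#' Relative improvement of a specificity-restricted AUC
#'
#' (auc90New - auc90Base) / (1 - auc90Base); negative when adaptation
#' degrades performance.
#'
#' @param auc90New,auc90Base the two AUC90 values; the baseline must be
#'   < 1.
#' @return the relative improvement (may be negative).
#' @export
relativeImprovement <- function(auc90New, auc90Base) {
  if (auc90Base >= 1) stop("baseline AUC90 must be < 1")
  (auc90New - auc90Base) / (1 - auc90Base)
}

#' Detection rate at a fixed false-detection budget
#'
#' Clinical event metrics are reported at a fixed false-detection rate:
#' this sweeps the decision threshold and returns the event detection rate
#' at the smallest threshold whose cohort-level false-detection rate stays
#' within the budget (counts are pooled over records).
#'
#' @param seriesList list of scored \linkS4class{ProbabilitySeries}, one
#'   per record.
#' @param records the matching list of \linkS4class{FeatureRecord}s.
#' @param fdBudget maximum false detections per hour (default 0.2).
#' @param minDurationS minimum detection duration (default 8 s).
#' @param thresholds candidate thresholds to sweep.
#' @return list with \code{threshold}, \code{gdr}, \code{fdPerHour} at the
#'   chosen operating point (threshold = NA if no candidate meets the
#'   budget).
#' @export
gdrAtFdBudget <- function(seriesList, records, fdBudget = 0.2,
                          minDurationS = 8,
                          thresholds = seq(0.05, 0.99, by = 0.01)) {
  stopifnot(length(seriesList) == length(records))
  hours <- vapply(records, recordHours, numeric(1))
  anns <- lapply(records, function(r) {
    labelsToEvents(epochLabels(r), epochHop(r))
  })
  for (th in sort(thresholds)) {
    nDet <- 0L; nTrue <- 0L; nFalse <- 0L
    for (i in seq_along(records)) {
      det <- thresholdToEvents(seriesList[[i]], th,
                               epochHop(records[[i]]), minDurationS)
      em <- eventMetrics(det, anns[[i]], hours[i])
      nDet <- nDet + em$nDetected
      nTrue <- nTrue + em$nTrueEvents
      nFalse <- nFalse + em$nFalse
    }
    fdh <- nFalse / sum(hours)
    if (fdh <= fdBudget) {
      return(list(threshold = th,
                  gdr = if (nTrue > 0) nDet / nTrue else NA_real_,
                  fdPerHour = fdh))
    }
  }
  list(threshold = NA_real_, gdr = NA_real_, fdPerHour = NA_real_)
}
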
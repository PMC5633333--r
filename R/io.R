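#' Write a feature table to delimited text
#'
#' One row per (channel, epoch): columns patient, channel, t_start, label,
#' f1..fD, comma-delimited, full floating-point precision, with a small
#' header block carrying the epoch geometry.
#'
#' @param record a \linkS4class{FeatureRecord}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(record, path) {
  D <- featureDim(record)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# seizAdapt feature table v1",
               paste0("# epoch_duration_s=", fmtFull(epochDuration(record))),
               paste0("# epoch_hop_s=", fmtFull(epochHop(record)))), con)
  writeLines(paste(c("patient", "channel", "t_start", "label",
                     paste0("f", seq_len(D))), collapse = ","), con)
  labs <- epochLabels(record)
  ts <- epochTimes(record)
  for (ch in seq_len(nChannels(record))) {
    X <- epochFeatures(record, ch)
    rows <- cbind(fmtFull(ts), format(labs, trim = TRUE),
                  matrix(fmtFull(X), nrow(X), D))
    writeLines(paste(patientID(record), paste0("ch", ch),
                     apply(rows, 1L, paste, collapse = ","), sep = ","), con)
  }
  invisible(path)
}

#' Read a feature table written by \code{\link{writeFeatureTable}}
#'
#' Malformed headers, ragged rows and labels outside {0,1} raise a parse
#' error naming the offending line; rows containing NaN features are
#' dropped with a warning.
#'
#' @param path input path.
#' @return a \linkS4class{FeatureRecord}.
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("parse error: empty file ", path)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(key, default) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(paste0("^# ", key, "="), "", hit[1]))
  }
  epochDur <- getMeta("epoch_duration_s", 8)
  epochHop <- getMeta("epoch_hop_s", 4)
  body <- which(!grepl("^#", lines))
  if (!length(body)) stop("parse error: no header row in ", path)
  headerLine <- body[1]
  header <- strsplit(lines[headerLine], ",", fixed = TRUE)[[1]]
  if (length(header) < 5L || !identical(header[1:4],
      c("patient", "channel", "t_start", "label"))) {
    stop("parse error at line ", headerLine, ": malformed header")
  }
  D <- length(header) - 4L
  dataLines <- body[-1]
  if (!length(dataLines)) stop("parse error: no data rows in ", path)
  fields <- strsplit(lines[dataLines], ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- dataLines[which(nf != length(header))[1]]
    stop("parse error at line ", bad, ": expected ", length(header),
         " fields, found ", nf[which(nf != length(header))[1]])
  }
  m <- do.call(rbind, fields)
  patient <- m[, 1]
  channel <- m[, 2]
  tStart <- as.numeric(m[, 3])
  labRaw <- m[, 4]
  lab <- suppressWarnings(as.numeric(labRaw))
  if (any(is.na(lab) | !(lab %in% c(0, 1)))) {
    bad <- dataLines[which(is.na(lab) | !(lab %in% c(0, 1)))[1]]
    stop("parse error at line ", bad, ": label must be 0 or 1")
  }
  feats <- suppressWarnings(
    matrix(as.numeric(m[, -(1:4), drop = FALSE]), nrow(m), D))
  nanRow <- apply(feats, 1L, function(r) any(is.nan(r) | is.na(r)))
  if (any(nanRow)) {
    # drop the affected epoch on every channel so channels stay aligned
    badT <- unique(tStart[nanRow])
    drop <- tStart %in% badT
    warning("dropping ", length(badT),
            " epoch(s) containing NaN features (lines ",
            paste(head(dataLines[nanRow], 5L), collapse = ", "), ")")
    m <- m[!drop, , drop = FALSE]
    feats <- feats[!drop, , drop = FALSE]
    tStart <- tStart[!drop]; lab <- lab[!drop]; channel <- channel[!drop]
    patient <- patient[!drop]
  }
  chans <- unique(channel)
  ord <- order(match(channel, chans), tStart)
  features <- list()
  labs <- NULL; ts <- NULL
  for (ch in chans) {
    sel <- channel == ch
    o <- order(tStart[sel])
    features[[ch]] <- feats[sel, , drop = FALSE][o, , drop = FALSE]
    if (is.null(labs)) {
      labs <- lab[sel][o]; ts <- tStart[sel][o]
    } else if (!isTRUE(all.equal(ts, tStart[sel][o])) ||
               !identical(labs, lab[sel][o])) {
      stop("parse error: channels disagree on epochs or labels")
    }
  }
  FeatureRecord(features, labs, ts, patientID = patient[1],
                epochDuration = epochDur, epochHop = epochHop)
}

#' Write seizure events as two-column delimited text
#' @param events data.frame with columns onset, offset (seconds); an
#'   optional peak column is written when present.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read seizure events from two-column delimited text
#' @param path input path.
#' @return data.frame with columns onset, offset.
#' @export
readAnnotation <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("onset", "offset") %in% colnames(df)))
  validateEvents(df[c("onset", "offset")])
}

# events must be positive-length, sorted and non-overlapping
validateEvents <- function(events) {
  if (nrow(events)) {
    stopifnot(all(events$onset < events$offset))
    if (is.unsorted(events$onset)) events <- events[order(events$onset), ]
    if (nrow(events) > 1 &&
        any(events$onset[-1] < events$offset[-nrow(events)])) {
      stop("events must be non-overlapping")
    }
  }
  events
}

#' Convert per-epoch labels to seizure events
#'
#' Maximal runs of 1-labelled epochs become intervals; the run spanning
#' epochs f..l (1-based) maps to ((f-1)*hop, l*hop) seconds.
#'
#' @param labels binary vector.
#' @param epochHopS hop between epoch starts (s).
#' @return data.frame with columns onset, offset (seconds).
#' @export
labelsToEvents <- function(labels, epochHopS) {
  stopifnot(all(labels %in% c(0, 1)))
  r <- rle(as.numeric(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values == 1
  data.frame(onset = (starts[sel] - 1L) * epochHopS,
             offset = ends[sel] * epochHopS)
}

#' Convert seizure events back to per-epoch labels
#'
#' Epoch i is labelled 1 iff its midpoint (i - 1/2) * hop lies inside an
#' event, the inverse of \code{\link{labelsToEvents}} (the two maps are
#' mutually inverse on label vectors).
#'
#' @param events data.frame with onset, offset columns (seconds).
#' @param N number of epochs.
#' @param epochHopS hop between epoch starts (s).
#' @return binary vector of length N.
#' @export
eventsToLabels <- function(events, N, epochHopS) {
  labels <- rep(0, N)
  mid <- (seq_len(N) - 0.5) * epochHopS
  for (e in seq_len(nrow(events))) {
    labels[mid >= events$onset[e] & mid < events$offset[e]] <- 1
  }
  labels
}

#' Subset a record to a contiguous epoch range
#' @param record a \linkS4class{FeatureRecord}.
#' @param idx contiguous, increasing epoch indices.
#' @return a \linkS4class{FeatureRecord} spanning those epochs.
#' @export
subsetEpochs <- function(record, idx) {
  stopifnot(length(idx) >= 1L, all(diff(idx) == 1L))
  out <- record[, idx]
  validObject(out)
  out
}
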
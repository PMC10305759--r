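#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase, so topography timing is preserved) to every channel of the
#' full continuous record. Filtering is done before any segmentation to
#' avoid edge effects at segment splices; when a recording already carries
#' multiple segments each is filtered separately.
#'
#' @param rec an [EEGRecording-class].
#' @param low,high band edges in Hz (defaults 0.5 and 40).
#' @return the filtered [EEGRecording-class].
#' @export
bandpass <- function(rec, low = 0.5, high = 40) {
  stopifnot(is(rec, "EEGRecording"))
  nyq <- rec@rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band must satisfy 0 < low < high < rate/2")
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  data <- rec@data
  starts <- segmentStarts(rec@segments)
  for (s in seq_along(starts)) {
    idx <- starts[s]:(starts[s] + rec@segments[s] - 1L)
    for (ch in seq_len(nrow(data))) {
      data[ch, idx] <- signal::filtfilt(bf, data[ch, idx])
    }
  }
  rec@data <- data
  rec@history <- c(rec@history, "bandpass")
  rec
}

#' Keep only the spans carrying a given annotation label
#'
#' Concatenates every annotated span (e.g. "eyes_closed") into one
#' recording while retaining the segment boundaries, so that downstream
#' stages never treat a splice between non-contiguous spans as continuous
#' data. Applied after filtering and before re-referencing.
#'
#' @param rec an [EEGRecording-class].
#' @param label annotation label to keep (default "eyes_closed").
#' @return the segmented [EEGRecording-class].
#' @export
selectSegments <- function(rec, label = "eyes_closed") {
  stopifnot(is(rec, "EEGRecording"))
  ann <- rec@annotations
  keep <- ann[ann$label == label, , drop = FALSE]
  if (!nrow(keep))
    stopIfNot(FALSE, sprintf("no usable segment: no '%s' annotation", label),
              class = "noUsableSegment")
  keep <- keep[order(keep$onset), , drop = FALSE]
  pieces <- list()
  lens <- integer()
  for (i in seq_len(nrow(keep))) {
    from <- floor(keep$onset[i] * rec@rate) + 1L
    to <- min(ncol(rec@data),
              floor((keep$onset[i] + keep$duration[i]) * rec@rate))
    if (to >= from) {
      pieces[[length(pieces) + 1L]] <- rec@data[, from:to, drop = FALSE]
      lens <- c(lens, to - from + 1L)
    }
  }
  if (!length(pieces))
    stopIfNot(FALSE, "no usable segment: annotated spans are empty",
              class = "noUsableSegment")
  rec@data <- do.call(cbind, pieces)
  rec@segments <- as.integer(lens)
  rec@annotations <- data.frame(onset = cumsum(c(0, head(lens, -1))) / rec@rate,
                                duration = lens / rec@rate,
                                label = label, stringsAsFactors = FALSE)
  rec@history <- c(rec@history, "select_segments")
  rec
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous channel mean at every sample and tags the
#' recording as average-referenced. Re-applying is refused (the subtraction
#' is idempotent in value, so a second application could only mask a
#' book-keeping error).
#'
#' @param rec an [EEGRecording-class] with reference "native".
#' @return the re-referenced [EEGRecording-class].
#' @export
averageReference <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@reference == "average")
    stop("recording is already average-referenced")
  rec@data <- sweep(rec@data, 2L, colMeans(rec@data))
  rec@reference <- "average"
  rec@history <- c(rec@history, "average_reference")
  rec
}

#' Interpolate a single bad channel (or refuse the recording)
#'
#' At most one artifacted channel is tolerated; its signal is replaced by
#' an inverse-squared-great-circle-distance weighted combination of all
#' good channels and the bad list is cleared. Recordings with more than one
#' bad channel are rejected with an exclusion error, mirroring the
#' screening rule for routine clinical EEG.
#'
#' @param rec an [EEGRecording-class].
#' @return the repaired [EEGRecording-class].
#' @export
interpolateBad <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (length(rec@bads) > 1L)
    stopIfNot(FALSE, sprintf(
      "exclude recording: %d artifacted channels (only one tolerated)",
      length(rec@bads)), class = "excludeRecording")
  if (length(rec@bads) == 1L) {
    bad <- match(rec@bads, rec@layout@channels)
    good <- setdiff(seq_len(nrow(rec@data)), bad)
    d <- greatCircleDist(rec@layout)[bad, good]
    w <- 1 / pmax(d, 1e-6)^2
    w <- w / sum(w)
    rec@data[bad, ] <- as.numeric(w %*% rec@data[good, , drop = FALSE])
    rec@bads <- character()
  }
  rec@history <- c(rec@history, "interpolate")
  rec
}

# Welch power spectral density, averaged periodograms over Hann windows.
# Windows never straddle a segment splice. Returns list(freq, psd) with
# psd a channels x freq matrix (power per Hz).
welchPsd <- function(data, rate, segments = ncol(data), windowSec = 2,
                     overlap = 0.5) {
  nwin <- as.integer(round(windowSec * rate))
  step <- max(1L, as.integer(round(nwin * (1 - overlap))))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))  # Hann
  norm <- sum(win^2) * rate
  nfreq <- nwin %/% 2L + 1L
  acc <- matrix(0, nrow(data), nfreq)
  count <- 0L
  starts <- segmentStarts(as.integer(segments))
  for (s in seq_along(starts)) {
    segLen <- segments[s]
    if (segLen < nwin) next
    for (off in seq(0L, segLen - nwin, by = step)) {
      idx <- (starts[s] + off):(starts[s] + off + nwin - 1L)
      seg <- sweep(data[, idx, drop = FALSE], 1L, rowMeans(data[, idx, drop = FALSE]))
      seg <- sweep(seg, 2L, win, `*`)
      ft <- t(apply(seg, 1L, fft))[, seq_len(nfreq), drop = FALSE]
      p <- (Mod(ft)^2) / norm
      p[, 2:(nfreq - 1L)] <- 2 * p[, 2:(nfreq - 1L)]  # one-sided
      acc <- acc + p
      count <- count + 1L
    }
  }
  if (count == 0L) stop("record too short for the PSD window")
  list(freq = seq(0, rate / 2, length.out = nfreq), psd = acc / count)
}

#' Alpha-dominance quality check via Welch PSD
#'
#' Computes the Welch power spectral density (2 s Hann windows, 50\%
#' overlap) averaged over channels and checks that mean power in the alpha
#' band (8-13 Hz) exceeds mean power in each of the delta (0.5-4), theta
#' (4-8) and beta (13-30 Hz) bands — the objective counterpart of the
#' visual "alpha-dominant resting rhythm" screen applied to eyes-closed
#' clinical EEG.
#'
#' @param rec an [EEGRecording-class] with at least 4 s of data.
#' @return a list of class \code{PSDReport}: \code{freq}, \code{psd}
#'   (channels x freq), \code{bandPower} (named: delta, theta, alpha,
#'   beta), \code{alphaDominant} (logical).
#' @export
alphaDominance <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (ncol(rec@data) / rec@rate < 4)
    stop("record too short for the alpha-dominance check (need >= 4 s)")
  w <- welchPsd(rec@data, rec@rate, rec@segments)
  meanPsd <- colMeans(w$psd)
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                beta = c(13, 30))
  bp <- vapply(bands, function(b) {
    sel <- w$freq >= b[1] & w$freq < b[2]
    mean(meanPsd[sel])
  }, numeric(1))
  out <- list(freq = w$freq, psd = w$psd, bandPower = bp,
              alphaDominant = bp[["alpha"]] > bp[["delta"]] &&
                bp[["alpha"]] > bp[["theta"]] &&
                bp[["alpha"]] > bp[["beta"]])
  class(out) <- "PSDReport"
  out
}

#' @export
print.PSDReport <- function(x, ...) {
  cat("PSDReport: band power (uV^2/Hz):",
      paste(sprintf("%s=%.3g", names(x$bandPower), x$bandPower),
            collapse = " "), "\n")
  cat("  alpha dominant:", x$alphaDominant, "\n")
  invisible(x)
}

#' Run the full preprocessing chain in its fixed order
#'
#' Band-pass filter the continuous record, keep the annotated eyes-closed
#' spans, re-reference to the average, interpolate at most one bad channel,
#' and run the alpha-dominance check. The order is asserted: this composed
#' entry point is the supported way to preprocess a raw recording.
#'
#' @param rec a raw [EEGRecording-class] (reference "native").
#' @param low,high band edges in Hz.
#' @param label annotation label of the spans to keep.
#' @return list: \code{recording} (preprocessed), \code{psd}
#'   (\code{PSDReport}), \code{alphaDominant} (logical).
#' @export
preprocessRecording <- function(rec, low = 0.5, high = 40,
                                label = "eyes_closed") {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@reference == "average")
    stop("preprocessRecording expects a native-referenced raw recording")
  out <- bandpass(rec, low, high)
  out <- selectSegments(out, label)
  out <- averageReference(out)
  out <- interpolateBad(out)
  expected <- c("bandpass", "select_segments", "average_reference", "interpolate")
  got <- out@history[out@history %in% expected]
  stopifnot(identical(got, expected))  # fixed pipeline order
  psd <- alphaDominance(out)
  list(recording = out, psd = psd, alphaDominant = psd$alphaDominant)
}
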
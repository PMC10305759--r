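#' Backfit reference maps to a recording
#'
#' Labels every sample with the reference map that best correlates
#' (in absolute value, so polarity is ignored) with the instantaneous
#' scalp topography. Samples with a flat (zero-variance) topography carry
#' the previous sample's label forward, or take the first subsequent valid
#' label at a segment start.
#'
#' @param rec an average-referenced [EEGRecording-class].
#' @param reference a [MicrostateMaps-class] on the same channels.
#' @return a [MicrostateLabels-class]; class names come from the reference
#'   labels (or M1..MK when unlabelled).
#' @export
backfit <- function(rec, reference) {
  stopifnot(is(rec, "EEGRecording"), is(reference, "MicrostateMaps"))
  if (rec@reference != "average")
    stop("backfitting requires an average-referenced recording")
  if (nChannels(rec) != nChannels(reference))
    stop("recording and reference maps must share the channel set")
  X <- sweep(rec@data, 2L, colMeans(rec@data))   # zero-mean per sample
  nrm <- sqrt(colSums(X^2))
  corr <- abs(reference@maps %*% X)              # K x samples, unnormalized
  lab <- max.col(t(corr), ties.method = "first")
  flat <- nrm < 1e-12 * max(nrm, 1)
  if (any(flat)) lab <- fillFlatSamples(lab, flat, rec@segments)
  cn <- reference@classLabels
  if (anyNA(cn)) cn <- paste0("M", seq_len(nMaps(reference)))
  new("MicrostateLabels", labels = as.integer(lab), rate = rec@rate,
      segments = rec@segments, classNames = cn)
}

# carry labels across zero-variance samples: previous-within-segment,
# else first subsequent valid label at a segment start
fillFlatSamples <- function(lab, flat, segments) {
  starts <- segmentStarts(segments)
  for (s in seq_along(starts)) {
    idx <- starts[s]:(starts[s] + segments[s] - 1L)
    f <- flat[idx]
    if (!any(f) || all(f)) next          # all-flat: keep argmax labels
    v <- lab[idx]
    firstValid <- which(!f)[1L]
    if (firstValid > 1L) {
      v[seq_len(firstValid - 1L)] <- v[firstValid]
      f[seq_len(firstValid - 1L)] <- FALSE
    }
    for (i in seq_along(v)) if (f[i]) v[i] <- v[i - 1L]
    lab[idx] <- v
  }
  lab
}

#' Temporal smoothing of a label sequence
#'
#' Sliding majority vote over a centered full window of
#' \code{round(windowMs * rate / 1000)} samples (21 samples for the default
#' 82 ms at 256 Hz), applied within contiguous segments only; ties keep the
#' incumbent label. The vote is iterated to a fixed point (at most 10
#' passes), which removes the brief inter-peak periods of low GFP that
#' would otherwise interrupt quasi-stable microstate segments.
#'
#' @param seq a [MicrostateLabels-class].
#' @param windowMs full window size in ms (default 82).
#' @param maxPasses iteration cap (default 10).
#' @return the smoothed [MicrostateLabels-class].
#' @export
smoothLabels <- function(seq, windowMs = 82, maxPasses = 10L) {
  stopifnot(is(seq, "MicrostateLabels"))
  if (windowMs <= 0) stop("windowMs must be positive")
  w <- as.integer(round(windowMs * seq@rate / 1000))
  if (w < 1L) stop("window shorter than one sample")
  if (w > min(seq@segments))
    stop("smoothing window longer than the shortest segment")
  half <- w %/% 2L
  K <- length(seq@classNames)
  lab <- seq@labels
  starts <- segmentStarts(seq@segments)
  for (pass in seq_len(maxPasses)) {
    changed <- FALSE
    for (s in seq_along(starts)) {
      idx <- starts[s]:(starts[s] + seq@segments[s] - 1L)
      v <- lab[idx]
      counts <- slidingCounts(v, K, half)
      best <- max.col(counts, ties.method = "first")
      keep <- counts[cbind(seq_along(v), v)] >= counts[cbind(seq_along(v), best)]
      newv <- ifelse(keep, v, best)     # tie (or win) -> incumbent stays
      if (any(newv != v)) changed <- TRUE
      lab[idx] <- newv
    }
    if (!changed) break
  }
  out <- seq
  out@labels <- as.integer(lab)
  out
}

# n x K matrix of class counts in the centered window [i-half, i+half],
# clipped at the sequence ends
slidingCounts <- function(v, K, half) {
  n <- length(v)
  counts <- matrix(0L, n, K)
  for (k in seq_len(K)) {
    ind <- as.integer(v == k)
    cs <- c(0L, cumsum(ind))
    lo <- pmax(0L, seq_len(n) - half - 1L)
    hi <- pmin(n, seq_len(n) + half)
    counts[, k] <- cs[hi + 1L] - cs[lo + 1L]
  }
  counts
}

#' Per-class microstate statistics of a label sequence
#'
#' Enumerates runs (maximal same-label spans within contiguous segments;
#' a run never spans a splice) and computes, per class: occurrence = runs
#' per second of analyzed time, coverage = percent of samples, and mean
#' duration = average run length in ms. A class with no run gets occurrence
#' 0, coverage 0 and a missing (NA) mean duration. Runs touching a segment
#' edge are counted like any other (a small truncation bias on mean
#' duration, noted here since edge runs are not observed in full).
#'
#' @param seq a non-empty [MicrostateLabels-class].
#' @return data.frame with columns class, occurrence (1/s), coverage (%),
#'   meanDuration (ms), nRuns; total analyzed time (s) as attribute
#'   \code{totalTime}.
#' @export
computeStats <- function(seq) {
  stopifnot(is(seq, "MicrostateLabels"))
  if (!length(seq@labels)) stop("empty label sequence")
  K <- length(seq@classNames)
  starts <- segmentStarts(seq@segments)
  runCount <- integer(K)
  runSamples <- integer(K)
  for (s in seq_along(starts)) {
    v <- seq@labels[starts[s]:(starts[s] + seq@segments[s] - 1L)]
    r <- rle(v)
    for (k in seq_len(K)) {
      sel <- r$values == k
      runCount[k] <- runCount[k] + sum(sel)
      runSamples[k] <- runSamples[k] + sum(r$lengths[sel])
    }
  }
  totalTime <- length(seq@labels) / seq@rate
  out <- data.frame(
    class = seq@classNames,
    occurrence = runCount / totalTime,
    coverage = 100 * runSamples / length(seq@labels),
    meanDuration = ifelse(runCount > 0,
                          1000 * (runSamples / runCount) / seq@rate,
                          NA_real_),
    nRuns = runCount,
    stringsAsFactors = FALSE)
  attr(out, "totalTime") <- totalTime
  out
}

#' C/D imbalance ratios
#'
#' Elementwise ratio of the class-C parameter over the class-D parameter
#' for occurrence, coverage and mean duration — the imbalance index between
#' the self-referential (C) and attentional (D) microstate modes. Ratios
#' are missing (with a warning) when the class-D denominator is zero or
#' missing.
#'
#' @param stats a per-class statistics data.frame from [computeStats()].
#' @param classC,classD class names of numerator and denominator.
#' @return data.frame with columns parameter, ratio.
#' @export
cdRatios <- function(stats, classC = "C", classD = "D") {
  rowC <- stats[stats$class == classC, , drop = FALSE]
  rowD <- stats[stats$class == classD, , drop = FALSE]
  if (nrow(rowC) != 1L || nrow(rowD) != 1L)
    stop("stats must contain exactly one row for each of classes ",
         classC, " and ", classD)
  params <- c("occurrence", "coverage", "meanDuration")
  ratio <- vapply(params, function(p) {
    den <- rowD[[p]]
    num <- rowC[[p]]
    if (is.na(den) || den == 0 || is.na(num)) NA_real_ else num / den
  }, numeric(1))
  if (anyNA(ratio))
    warning("class-", classD,
            " denominator missing or zero; ratio set to NA")
  data.frame(parameter = params, ratio = unname(ratio),
             stringsAsFactors = FALSE)
}

#' Per-subject statistics table for a whole cohort
#'
#' Backfits a reference map set to every recording, smooths the label
#' sequences, and assembles the tidy per-subject, per-class statistics
#' table plus the C/D ratio table that the group-comparison stage consumes.
#'
#' @param recordings named list of average-referenced
#'   [EEGRecording-class] objects.
#' @param reference a labelled [MicrostateMaps-class].
#' @param groups named character vector mapping subject id to group.
#' @param windowMs smoothing window (ms); \code{NULL} skips smoothing.
#' @return list: \code{stats} (subject, group, class, occurrence, coverage,
#'   meanDuration, nRuns), \code{ratios} (subject, group, parameter,
#'   ratio), \code{labels} (list of smoothed [MicrostateLabels-class]).
#' @export
cohortStats <- function(recordings, reference, groups, windowMs = 82) {
  statsRows <- list()
  ratioRows <- list()
  labelsList <- list()
  for (id in names(recordings)) {
    lab <- backfit(recordings[[id]], reference)
    if (!is.null(windowMs)) lab <- smoothLabels(lab, windowMs)
    st <- computeStats(lab)
    st$subject <- id
    st$group <- unname(groups[id])
    rt <- suppressWarnings(cdRatios(st))
    rt$subject <- id
    rt$group <- unname(groups[id])
    statsRows[[id]] <- st
    ratioRows[[id]] <- rt
    labelsList[[id]] <- lab
  }
  stats <- do.call(rbind, c(statsRows, make.row.names = FALSE))
  ratios <- do.call(rbind, c(ratioRows, make.row.names = FALSE))
  list(stats = stats[, c("subject", "group", "class", "occurrence",
                         "coverage", "meanDuration", "nRuns")],
       ratios = ratios[, c("subject", "group", "parameter", "ratio")],
       labels = labelsList)
}
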
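#' @describeIn SensorLayout number of channels
#' @param x,object an object of the documented class.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @export
setMethod("nChannels", "SensorLayout", function(x) length(x@channels))

#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))

#' @export
setMethod("nChannels", "MicrostateMaps", function(x) ncol(x@maps))

#' Channel names of an object
#' @param x a SensorLayout, EEGRecording or MicrostateMaps.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @export
setMethod("channelNames", "SensorLayout", function(x) x@channels)

#' @export
setMethod("channelNames", "EEGRecording", function(x) x@layout@channels)

#' @export
setMethod("channelNames", "MicrostateMaps", function(x) x@channels)

#' Sampling rate in Hz
#' @param x an object carrying a sampling rate.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)

#' @export
setMethod("samplingRate", "GFPSeries", function(x) x@rate)

#' @export
setMethod("samplingRate", "MicrostateLabels", function(x) x@rate)

#' Number of samples
#' @param x an object with a time axis.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

#' @export
setMethod("nSamples", "GFPSeries", function(x) length(x@values))

#' @export
setMethod("nSamples", "MicrostateLabels", function(x) length(x@labels))

#' Signal matrix of a recording (channels x samples, microvolts)
#' @param x an EEGRecording.
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @export
setMethod("signalData", "EEGRecording", function(x) x@data)

#' Contiguous-segment lengths (in samples)
#' @param x an object carrying segment structure.
#' @export
setGeneric("segmentLengths", function(x) standardGeneric("segmentLengths"))

#' @export
setMethod("segmentLengths", "EEGRecording", function(x) x@segments)

#' @export
setMethod("segmentLengths", "GFPSeries", function(x) x@segments)

#' @export
setMethod("segmentLengths", "MicrostateLabels", function(x) x@segments)

#' Reference state of a recording ("native" or "average")
#' @param x an EEGRecording.
#' @export
setGeneric("referenceState", function(x) standardGeneric("referenceState"))

#' @export
setMethod("referenceState", "EEGRecording", function(x) x@reference)

#' Annotations of a recording
#' @param x an EEGRecording.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @export
setMethod("annotations", "EEGRecording", function(x) x@annotations)

#' Bad-channel list
#' @param x an EEGRecording.
#' @export
setGeneric("badChannels", function(x) standardGeneric("badChannels"))

#' @export
setMethod("badChannels", "EEGRecording", function(x) x@bads)

#' Replace the bad-channel list
#' @param x an EEGRecording.
#' @param value character vector of channel names.
#' @export
setGeneric("badChannels<-", function(x, value) standardGeneric("badChannels<-"))

#' @export
setMethod("badChannels<-", "EEGRecording", function(x, value) {
  x@bads <- as.character(value)
  validObject(x)
  x
})

#' Topography matrix of a map set (K x channels)
#' @param x a MicrostateMaps or ClusterFit.
#' @export
setGeneric("mapMatrix", function(x) standardGeneric("mapMatrix"))

#' @export
setMethod("mapMatrix", "MicrostateMaps", function(x) x@maps)

#' @export
setMethod("mapMatrix", "ClusterFit", function(x) x@mapset@maps)

#' Class labels of a map set or label sequence
#' @param x a MicrostateMaps or MicrostateLabels.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setMethod("classLabels", "MicrostateMaps", function(x) x@classLabels)

#' @export
setMethod("classLabels", "MicrostateLabels", function(x) x@classNames)

#' Number of maps in a set
#' @param x a MicrostateMaps.
#' @export
setGeneric("nMaps", function(x) standardGeneric("nMaps"))

#' @export
setMethod("nMaps", "MicrostateMaps", function(x) nrow(x@maps))

#' GFP values of a series
#' @param x a GFPSeries.
#' @export
setGeneric("gfpValues", function(x) standardGeneric("gfpValues"))

#' @export
setMethod("gfpValues", "GFPSeries", function(x) x@values)

#' Per-sample label vector
#' @param x a MicrostateLabels.
#' @export
setGeneric("labelVector", function(x) standardGeneric("labelVector"))

#' @export
setMethod("labelVector", "MicrostateLabels", function(x) x@labels)

#' Global explained variance of a fit
#' @param x a ClusterFit.
#' @export
setGeneric("gev", function(x) standardGeneric("gev"))

#' @export
setMethod("gev", "ClusterFit", function(x) x@gev)

#' Posterior draws of a BestFit
#' @param x a BestFit.
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' @export
setMethod("posteriorDraws", "BestFit", function(x) x@draws)

#' Posterior mean effect size of a BestFit
#' @param x a BestFit.
#' @export
setGeneric("effectSize", function(x) standardGeneric("effectSize"))

#' @export
setMethod("effectSize", "BestFit", function(x) x@effectSize)

#' Posterior probability outside the ROPE
#' @param x a BestFit.
#' @export
setGeneric("pOutsideRope", function(x) standardGeneric("pOutsideRope"))

#' @export
setMethod("pOutsideRope", "BestFit", function(x) x@pOutsideRope)

#' Is the comparison significant at the configured threshold?
#' @param x a BestFit.
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @export
setMethod("isSignificant", "BestFit", function(x) x@significant)

#' Subset a map set
#' @param x a MicrostateMaps.
#' @param i map indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MicrostateMaps", function(x, i, j, ..., drop = FALSE) {
  initialize(x, maps = x@maps[i, , drop = FALSE],
             classLabels = x@classLabels[i])
})

setMethod("show", "SensorLayout", function(object) {
  cat("SensorLayout with", length(object@channels), "channels:",
      paste(head(object@channels, 6L), collapse = ", "),
      if (length(object@channels) > 6L) "..." else "", "\n")
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(object@data), ncol(object@data),
              ncol(object@data) / object@rate, object@rate))
  cat(sprintf("  reference: %s | segments: %d | bads: %s\n",
              object@reference, length(object@segments),
              if (length(object@bads)) paste(object@bads, collapse = ", ")
              else "none"))
  if (nrow(object@annotations))
    cat("  annotations:", paste(unique(object@annotations$label), collapse = ", "), "\n")
})

setMethod("show", "MicrostateMaps", function(object) {
  lab <- ifelse(is.na(object@classLabels), "?", object@classLabels)
  cat(sprintf("MicrostateMaps: %d maps x %d channels [%s] (%s)\n",
              nrow(object@maps), ncol(object@maps),
              paste(lab, collapse = " "), object@provenance))
})

setMethod("show", "GFPSeries", function(object) {
  cat(sprintf("GFPSeries: %d samples at %g Hz, %d segment(s), mean %.3g uV\n",
              length(object@values), object@rate, length(object@segments),
              mean(object@values)))
})

setMethod("show", "ClusterFit", function(object) {
  cat(sprintf("ClusterFit: K=%d, GEV=%.4f, %d iterations (%s)\n",
              nrow(object@mapset@maps), object@gev, object@nIter,
              if (object@converged) "converged" else "iteration cap"))
})

setMethod("show", "MicrostateLabels", function(object) {
  cov <- round(100 * tabulate(object@labels, length(object@classNames)) /
                 max(1L, length(object@labels)), 1)
  cat(sprintf("MicrostateLabels: %d samples at %g Hz, classes %s, coverage %s\n",
              length(object@labels), object@rate,
              paste(object@classNames, collapse = "/"),
              paste(sprintf("%s=%.1f%%", object@classNames, cov), collapse = " ")))
})

setMethod("show", "BestFit", function(object) {
  cat(sprintf("BestFit: effect size d = %.3f, %d%% HDI [%.3f, %.3f]\n",
              object@effectSize, round(100 * object@hdiMass),
              object@hdi[1], object@hdi[2]))
  cat(sprintf("  P(outside ROPE [%.2f, %.2f]) = %.3f -> %s\n",
              object@rope[1], object@rope[2], object@pOutsideRope,
              if (object@significant) "credible difference" else "no decision"))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %s; %g s at %g Hz, snr=%g, seed=%d\n",
              paste(sprintf("%s(n=%d)", object@groups$name, object@groups$n),
                    collapse = " + "),
              object@lengthSec, object@rate, object@snr, object@seed))
})
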
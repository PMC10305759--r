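#' Sensor layout for a 10-20 electrode montage
#'
#' Holds channel names together with their positions on the unit sphere and
#' an azimuthal-equidistant 2D projection used for plotting and for
#' distance-weighted channel interpolation.
#'
#' @slot channels character vector of channel names.
#' @slot pos3 numeric matrix (channels x 3) of unit-sphere coordinates;
#'   x points to the right ear, y to the nasion, z to the vertex.
#' @slot pos2 numeric matrix (channels x 2), flat projection of \code{pos3}.
#'
#' @seealso [makeLayout()]
#' @export
setClass("SensorLayout",
  representation(channels = "character", pos3 = "matrix", pos2 = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- length(object@channels)
    if (anyDuplicated(object@channels)) msg <- c(msg, "duplicate channel names")
    if (nrow(object@pos3) != n || ncol(object@pos3) != 3L)
      msg <- c(msg, "pos3 must be channels x 3")
    if (nrow(object@pos2) != n || ncol(object@pos2) != 2L)
      msg <- c(msg, "pos2 must be channels x 2")
    if (nrow(object@pos3) == n && ncol(object@pos3) == 3L) {
      nrm <- sqrt(rowSums(object@pos3^2))
      if (any(abs(nrm - 1) > 1e-9))
        msg <- c(msg, "pos3 rows must lie on the unit sphere (|norm - 1| <= 1e-9)")
    }
    if (length(msg)) msg else TRUE
  })

#' Multichannel EEG recording
#'
#' A channels x samples matrix in microvolts plus the metadata the
#' preprocessing and microstate stages need: sampling rate, sensor layout,
#' annotations, bad-channel list, reference state and the contiguous-segment
#' structure (so that later stages never treat a splice between concatenated
#' segments as continuous data).
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot rate sampling rate in Hz.
#' @slot layout a [SensorLayout-class].
#' @slot annotations data.frame with columns onset (s), duration (s), label.
#' @slot bads character vector of bad channel names.
#' @slot reference "native" or "average".
#' @slot segments integer vector of contiguous-segment lengths (samples);
#'   sums to the number of columns of \code{data}.
#' @slot history character vector of processing steps applied so far.
#' @export
setClass("EEGRecording",
  representation(data = "matrix", rate = "numeric", layout = "SensorLayout",
                 annotations = "data.frame", bads = "character",
                 reference = "character", segments = "integer",
                 history = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@data) != length(object@layout@channels))
      msg <- c(msg, "data row count must equal layout channel count")
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be a single positive number")
    if (!object@reference %in% c("native", "average"))
      msg <- c(msg, "reference must be 'native' or 'average'")
    if (sum(object@segments) != ncol(object@data))
      msg <- c(msg, "segment lengths must sum to the sample count")
    if (any(object@segments < 1L)) msg <- c(msg, "empty segment")
    if (nrow(object@annotations)) {
      need <- c("onset", "duration", "label")
      if (!all(need %in% names(object@annotations))) {
        msg <- c(msg, "annotations need onset, duration, label columns")
      } else {
        tmax <- ncol(object@data) / object@rate
        if (any(object@annotations$onset < 0) ||
            any(object@annotations$onset + object@annotations$duration > tmax + 1e-6))
          msg <- c(msg, "annotations outside record bounds")
      }
    }
    if (!all(object@bads %in% object@layout@channels))
      msg <- c(msg, "bads must name layout channels")
    if (length(msg)) msg else TRUE
  })

#' A set of microstate topographies
#'
#' K topographic maps, each a zero-mean unit-norm vector over channels.
#' Maps may carry class labels (canonically A-D) and a provenance tag
#' recording whether they came from one subject, a group-level clustering,
#' or a canonical template.
#'
#' @slot maps numeric matrix, K x channels; rows zero-mean, unit L2 norm.
#' @slot classLabels character of length K (NA when unlabelled).
#' @slot channels character vector of channel names (column order of maps).
#' @slot provenance character tag, e.g. "subject:sub-001", "group:CTRL",
#'   "template".
#' @slot metadata list for ancillary results (e.g. correlations to a
#'   reference set established by [labelMaps()]).
#' @export
setClass("MicrostateMaps",
  representation(maps = "matrix", classLabels = "character",
                 channels = "character", provenance = "character",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@maps) < 1L) msg <- c(msg, "need at least one map")
    if (ncol(object@maps) != length(object@channels))
      msg <- c(msg, "map columns must match channel names")
    if (length(object@classLabels) != nrow(object@maps))
      msg <- c(msg, "one class label (possibly NA) per map")
    if (ncol(object@maps) > 1L) {
      if (any(abs(rowMeans(object@maps)) > 1e-9))
        msg <- c(msg, "map rows must be zero-mean (tol 1e-9)")
      if (any(abs(sqrt(rowSums(object@maps^2)) - 1) > 1e-9))
        msg <- c(msg, "map rows must be unit-norm (tol 1e-9)")
    }
    if (length(msg)) msg else TRUE
  })

#' Global field power series
#'
#' Per-sample spatial standard deviation of an average-referenced recording,
#' with the sampling rate and segment structure carried along so that peak
#' picking never crosses a splice.
#'
#' @slot values numeric vector of GFP values (microvolts), one per sample.
#' @slot rate sampling rate in Hz.
#' @slot segments integer vector of contiguous-segment lengths.
#' @export
setClass("GFPSeries",
  representation(values = "numeric", rate = "numeric", segments = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@values < 0)) msg <- c(msg, "GFP values must be >= 0")
    if (sum(object@segments) != length(object@values))
      msg <- c(msg, "segment lengths must sum to series length")
    if (length(msg)) msg else TRUE
  })

#' Result of a modified K-means fit
#'
#' @slot mapset the fitted [MicrostateMaps-class].
#' @slot assignments integer vector: cluster index per input peak map.
#' @slot gev global explained variance of the fit, in [0, 1].
#' @slot gevTrace numeric vector, GEV after each iteration of the winning
#'   restart (non-decreasing by construction).
#' @slot nIter iterations used by the winning restart.
#' @slot converged TRUE if the winning restart met the tolerance before
#'   the iteration cap.
#' @export
setClass("ClusterFit",
  representation(mapset = "MicrostateMaps", assignments = "integer",
                 gev = "numeric", gevTrace = "numeric", nIter = "integer",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@gev < -1e-12 || object@gev > 1 + 1e-12)
      msg <- c(msg, "GEV must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Per-sample microstate label sequence
#'
#' @slot labels integer vector of class indices in 1..K, one per sample.
#' @slot rate sampling rate in Hz.
#' @slot segments integer vector of contiguous-segment lengths.
#' @slot classNames character vector of length K naming the classes.
#' @export
setClass("MicrostateLabels",
  representation(labels = "integer", rate = "numeric", segments = "integer",
                 classNames = "character"),
  validity = function(object) {
    msg <- character()
    if (anyNA(object@labels)) msg <- c(msg, "every sample must be labelled")
    if (length(object@labels) &&
        (min(object@labels) < 1L || max(object@labels) > length(object@classNames)))
      msg <- c(msg, "labels must index classNames")
    if (sum(object@segments) != length(object@labels))
      msg <- c(msg, "segment lengths must sum to label count")
    if (length(msg)) msg else TRUE
  })

#' Posterior summary of a robust Bayesian two-group comparison
#'
#' Holds the MCMC draws and decision quantities of the robust t-model
#' comparison: group means and SDs, the shared normality parameter, the
#' standardized effect size with its highest-density interval, and the
#' posterior probability that the effect size lies outside the region of
#' practical equivalence (ROPE).
#'
#' @slot draws data.frame of posterior draws (mu1, mu2, sigma1, sigma2, nu, d).
#' @slot rope numeric length-2, the ROPE bounds on the effect-size scale.
#' @slot hdiMass probability mass of the reported HDI.
#' @slot effectSize posterior mean of d.
#' @slot hdi numeric length-2, HDI of d.
#' @slot pOutsideRope posterior probability that |d| is outside the ROPE.
#' @slot significant TRUE when pOutsideRope meets the decision threshold.
#' @slot threshold the decision threshold used.
#' @slot diagnostics list: effective sample size, split-Rhat (when >1 chain),
#'   and a convergence flag.
#' @export
setClass("BestFit",
  representation(draws = "data.frame", rope = "numeric", hdiMass = "numeric",
                 effectSize = "numeric", hdi = "numeric",
                 pOutsideRope = "numeric", significant = "logical",
                 threshold = "numeric", diagnostics = "list"),
  validity = function(object) {
    msg <- character()
    if (object@pOutsideRope < 0 || object@pOutsideRope > 1)
      msg <- c(msg, "pOutsideRope must be in [0, 1]")
    if (length(object@hdi) != 2L || object@hdi[1] > object@hdi[2])
      msg <- c(msg, "hdi must be an ordered pair")
    if (length(msg)) msg else TRUE
  })

#' Specification of a synthetic EEG cohort
#'
#' Describes the generative conditions for a simulated resting-state cohort:
#' group sizes, per-class mean sojourn durations and occurrence weights,
#' per-group multiplicative perturbations of those class parameters (to
#' encode e.g. a class-D reduction in a disease-like group), the sojourn
#' dispersion, signal-to-noise ratio, record length, sampling rate and seed.
#'
#' @slot groups data.frame with columns name, n.
#' @slot classNames character, e.g. c("A","B","C","D").
#' @slot meanDurationMs named numeric, target mean sojourn per class (ms).
#' @slot occurrenceWeights named numeric, relative entry weights per class.
#' @slot durationScale numeric matrix groups x classes, multiplicative on
#'   mean duration (1 = control conditions).
#' @slot occurrenceScale numeric matrix groups x classes, multiplicative on
#'   occurrence weights.
#' @slot gammaShape shape of the gamma sojourn distribution.
#' @slot snr state-signal RMS over noise RMS (Inf = noiseless).
#' @slot lengthSec record length per subject (s).
#' @slot rate sampling rate (Hz).
#' @slot seed master integer seed.
#' @export
setClass("CohortSpec",
  representation(groups = "data.frame", classNames = "character",
                 meanDurationMs = "numeric", occurrenceWeights = "numeric",
                 durationScale = "matrix", occurrenceScale = "matrix",
                 gammaShape = "numeric", snr = "numeric", lengthSec = "numeric",
                 rate = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@groups) < 1L) msg <- c(msg, "need at least one group")
    if (any(object@groups$n < 1L)) msg <- c(msg, "n_subjects must be >= 1")
    if (any(object@meanDurationMs <= 0)) msg <- c(msg, "durations must be > 0")
    if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
    if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
    if (object@lengthSec <= 0) msg <- c(msg, "lengthSec must be > 0")
    K <- length(object@classNames)
    if (length(object@meanDurationMs) != K ||
        length(object@occurrenceWeights) != K)
      msg <- c(msg, "per-class parameters must match classNames")
    if (!all(dim(object@durationScale) == c(nrow(object@groups), K)) ||
        !all(dim(object@occurrenceScale) == c(nrow(object@groups), K)))
      msg <- c(msg, "scale matrices must be groups x classes")
    if (all(object@occurrenceWeights <= 0))
      msg <- c(msg, "at least one occurrence weight must be positive")
    if (length(msg)) msg else TRUE
  })
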
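#' Canonical template topographies for classes A-D
#'
#' Constructs four smooth topographies qualitatively matching the canonical
#' microstate classes on the given layout: A with a left-posterior to
#' right-anterior diagonal axis, B its mirror image (right-posterior to
#' left-anterior), C an anterior-negative / posterior-positive symmetric
#' gradient, and D a fronto-central maximum against the periphery. A small
#' seeded, spatially smooth perturbation is added so that different seeds
#' give slightly different (but still canonical) generating maps. Each map
#' is zero-mean and unit-norm over channels; construction fails if any pair
#' exceeds an absolute spatial correlation of 0.7.
#'
#' @param layout a [SensorLayout-class].
#' @param seed integer seed for the perturbation.
#' @param perturbation relative magnitude of the smooth random component
#'   (0 gives the deterministic canonical patterns).
#' @return a [MicrostateMaps-class] with labels A-D, provenance "template".
#' @examples
#' maps <- makeTemplateMaps(makeLayout(), seed = 1)
#' range(abs(rowMeans(mapMatrix(maps))))
#' @export
makeTemplateMaps <- function(layout, seed = 1L, perturbation = 0.12) {
  stopifnot(is(layout, "SensorLayout"))
  p <- layout@pos3
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  a <- 35 * pi / 180  # diagonal axis of classes A/B
  raw <- rbind(
    A = cos(a) * x + sin(a) * y,
    B = -cos(a) * x + sin(a) * y,
    C = -y,
    D = z + 0.3 * y)
  pert <- 0
  if (perturbation > 0) {
    # spatially smooth random field: kernel-smoothed white noise on the cap
    D2 <- greatCircleDist(layout)
    Ksm <- exp(-(D2 / 0.8)^2)
    pert <- withSeed(mixSeed(seed, 211L), {
      matrix(rnorm(4L * nrow(p)), 4L) %*% Ksm
    })
    pert <- pert / sqrt(rowSums(pert^2))
  }
  base <- raw / sqrt(rowSums(raw^2))
  # the canonical separation bound is a hard invariant; the perturbation
  # scale is cosmetic, so it is halved until the bound holds
  for (shrink in perturbation * 0.5^(0:6)) {
    out <- base + shrink * pert
    out <- out - rowMeans(out)
    out <- out / sqrt(rowSums(out^2))
    cc <- abs(cor(t(out)))
    diag(cc) <- 0
    if (max(cc) <= 0.7) break
  }
  raw <- out
  if (max(cc) > 0.7)
    stop("template maps violate the pairwise |correlation| <= 0.7 bound")
  new("MicrostateMaps", maps = raw, classLabels = c("A", "B", "C", "D"),
      channels = layout@channels, provenance = "template",
      metadata = list(seed = seed))
}

#' Simulate a microstate label sequence
#'
#' Draws a semi-Markov sequence of class indices: sojourn lengths come from
#' a gamma distribution with the class's target mean duration (shape
#' \code{gammaShape}, so the mean is the target and dispersion is realistic
#' for ~100 ms microstates), and each transition draws the next class from
#' the occurrence weights with the current class excluded (no self
#' transitions, so sojourns are genuine).
#'
#' @param meanDurationMs named numeric, target mean sojourn per class (ms).
#' @param occurrenceWeights numeric, relative entry weights (same length).
#' @param rate sampling rate (Hz).
#' @param nSamples number of samples to generate.
#' @param seed integer seed.
#' @param gammaShape gamma shape of the sojourn distribution (default 2).
#' @param classNames optional class names (defaults to names of
#'   \code{meanDurationMs}, or LETTERS).
#' @return a [MicrostateLabels-class] of length \code{nSamples}.
#' @examples
#' seq <- simulateLabelSequence(c(A = 100, B = 100), c(1, 1), 256, 1000, seed = 1)
#' table(labelVector(seq))
#' @export
simulateLabelSequence <- function(meanDurationMs, occurrenceWeights, rate,
                                  nSamples, seed = 1L, gammaShape = 2,
                                  classNames = NULL) {
  K <- length(meanDurationMs)
  stopifnot(length(occurrenceWeights) == K, nSamples >= 1, rate > 0)
  if (any(meanDurationMs <= 0)) stop("mean durations must be positive")
  if (all(occurrenceWeights <= 0)) stop("all occurrence weights are zero")
  if (is.null(classNames)) {
    classNames <- names(meanDurationMs)
    if (is.null(classNames)) classNames <- LETTERS[seq_len(K)]
  }
  meanSamples <- meanDurationMs * rate / 1000
  w <- pmax(occurrenceWeights, 0)
  labels <- integer(nSamples)
  withSeed(seed, {
    cur <- sample.int(K, 1L, prob = w)
    pos <- 1L
    while (pos <= nSamples) {
      len <- max(1L, as.integer(round(
        rgamma(1L, shape = gammaShape, scale = meanSamples[cur] / gammaShape))))
      end <- min(nSamples, pos + len - 1L)
      labels[pos:end] <- cur
      pos <- end + 1L
      if (K > 1L) {
        wNext <- w
        wNext[cur] <- 0
        if (all(wNext == 0)) wNext <- rep(1, K) # lone positive weight: uniform restart
        cur <- sample.int(K, 1L, prob = wNext)
      }
    }
  })
  new("MicrostateLabels", labels = labels, rate = rate,
      segments = as.integer(nSamples), classNames = classNames)
}

#' Render a multichannel EEG from a label sequence and maps
#'
#' Forward model for eyes-closed resting EEG: at each sample the active
#' class's topography is driven by a 10 Hz alpha carrier with a slowly
#' varying random (log-Ornstein-Uhlenbeck) envelope; topography polarity
#' flips at random per sojourn (microstate analysis is polarity-invariant
#' for spontaneous EEG and this exercises that invariance). Additive noise
#' is spatially independent 1/f-shaped background scaled so that
#' state-signal RMS over noise RMS equals \code{snr}. The output is
#' average-referenced.
#'
#' @param labels a [MicrostateLabels-class].
#' @param maps a [MicrostateMaps-class]; classes must match the label set.
#' @param rate sampling rate (Hz); defaults to the label sequence's.
#' @param snr state-signal RMS / noise RMS; \code{Inf} disables noise.
#' @param seed integer seed.
#' @param amplitude RMS scale of the alpha carrier in microvolts.
#' @return an [EEGRecording-class] (reference "average") with a single
#'   "eyes_closed" annotation spanning the whole record.
#' @export
renderEEG <- function(labels, maps, rate = samplingRate(labels), snr = 4,
                      seed = 1L, amplitude = 15) {
  stopifnot(is(labels, "MicrostateLabels"), is(maps, "MicrostateMaps"))
  K <- nMaps(maps)
  if (length(labels@classNames) != K)
    stop("label sequence and map set disagree on the number of classes")
  if (snr <= 0) stop("snr must be positive")
  lv <- labels@labels
  n <- length(lv)
  C <- nChannels(maps)
  t <- (seq_len(n) - 1) / rate
  withSeed(mixSeed(seed, 17L), {
    # alpha carrier with slowly varying log-OU envelope (tau = 0.5 s)
    phi <- runif(1L, 0, 2 * pi)
    rho <- exp(-1 / (0.5 * rate))
    innov <- rnorm(n, sd = sqrt(1 - rho^2) * 0.5)
    ou <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    env <- exp(ou - mean(ou))
    carrier <- amplitude * sqrt(2) * sin(2 * pi * 10 * t + phi) * env
    # per-sojourn polarity flips
    runs <- rle(lv)
    flips <- rep(sample(c(-1, 1), length(runs$lengths), replace = TRUE),
                 runs$lengths)
    clean <- maps@maps[lv, , drop = FALSE] * (carrier * flips)
    clean <- t(clean)  # channels x samples
    if (is.finite(snr)) {
      noise <- oneOverFNoise(C, n, rate)
      noise <- noise * (sqrt(mean(clean^2)) / sqrt(mean(noise^2)) / snr)
      data <- clean + noise
    } else {
      data <- clean
    }
    data <- sweep(data, 2L, colMeans(data))  # enforce average reference
    rownames(data) <- maps@channels
    lay <- makeLayout()
    if (!identical(lay@channels, maps@channels)) {
      # maps rendered on a non-canonical layout: build a matching layout stub
      stop("renderEEG requires maps defined on the canonical 19-channel layout")
    }
    new("EEGRecording", data = data, rate = rate, layout = lay,
        annotations = data.frame(onset = 0, duration = n / rate,
                                 label = "eyes_closed",
                                 stringsAsFactors = FALSE),
        bads = character(), reference = "average",
        segments = as.integer(n), history = c("simulate", "average_reference"))
  })
}

# spatially independent 1/f-shaped Gaussian noise, channels x samples
oneOverFNoise <- function(nChannels, nSamples, rate) {
  freqs <- seq(0, rate, length.out = nSamples + 1L)[seq_len(nSamples)]
  fold <- pmin(freqs, rate - freqs)          # two-sided spectrum
  amp <- 1 / sqrt(pmax(fold, 1))             # power ~ 1/f, floored at 1 Hz
  amp[1L] <- 0                               # no DC
  out <- matrix(0, nChannels, nSamples)
  for (ch in seq_len(nChannels)) {
    spec <- fft(rnorm(nSamples)) * amp
    out[ch, ] <- Re(fft(spec, inverse = TRUE)) / nSamples
  }
  out
}

#' Construct a synthetic-cohort specification
#'
#' Defaults encode an eyes-closed resting cohort with four canonical classes
#' at ~100 ms mean sojourns and equal occurrence weights, 60 s records at
#' 256 Hz and an SNR of 4. Group-level perturbations are multiplicative on
#' the per-class mean duration and occurrence weight, so e.g.
#' \code{durationScale = list(DIS = c(D = 0.6))} gives a disease-like group
#' whose class-D sojourns are 40\% shorter than the control group's.
#'
#' @param groups named integer vector: subjects per group, first group is
#'   the control/reference group.
#' @param meanDurationMs named numeric, per-class target mean sojourn (ms).
#' @param occurrenceWeights numeric, per-class relative entry weights.
#' @param durationScale named list: group -> named numeric of multiplicative
#'   factors on the class mean durations.
#' @param occurrenceScale same structure, applied to occurrence weights.
#' @param gammaShape gamma shape of the sojourn law.
#' @param snr state-signal RMS / noise RMS.
#' @param lengthSec record length per subject (s).
#' @param rate sampling rate (Hz).
#' @param seed master integer seed.
#' @return a [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(c(CTRL = 5, DIS = 5),
#'                    durationScale = list(DIS = c(D = 0.6)))
#' spec
#' @export
cohortSpec <- function(groups = c(CTRL = 10),
                       meanDurationMs = c(A = 100, B = 100, C = 100, D = 100),
                       occurrenceWeights = rep(1, length(meanDurationMs)),
                       durationScale = list(), occurrenceScale = list(),
                       gammaShape = 2, snr = 4, lengthSec = 60, rate = 256,
                       seed = 1L) {
  classNames <- names(meanDurationMs)
  if (is.null(classNames)) classNames <- LETTERS[seq_along(meanDurationMs)]
  grp <- data.frame(name = names(groups), n = as.integer(groups),
                    stringsAsFactors = FALSE)
  if (is.null(grp$name)) stop("groups must be a named vector")
  expand <- function(lst) {
    m <- matrix(1, nrow(grp), length(classNames),
                dimnames = list(grp$name, classNames))
    for (g in names(lst)) {
      if (!g %in% grp$name) stop("unknown group in scale list: ", g)
      v <- lst[[g]]
      if (is.null(names(v))) stop("scale factors must be named by class")
      m[g, names(v)] <- v
    }
    m
  }
  new("CohortSpec", groups = grp, classNames = classNames,
      meanDurationMs = stats::setNames(meanDurationMs, classNames),
      occurrenceWeights = stats::setNames(occurrenceWeights, classNames),
      durationScale = expand(durationScale),
      occurrenceScale = expand(occurrenceScale),
      gammaShape = gammaShape, snr = snr, lengthSec = lengthSec,
      rate = rate, seed = as.numeric(seed))
}

#' Simulate a cohort of EEG recordings with known ground truth
#'
#' One recording per subject, generated with the group's perturbed class
#' parameters. The returned ground truth carries the generating maps, the
#' true label sequences, per-subject per-class statistics computed from
#' those true sequences, realized between-group effect sizes (Cohen's d
#' against the first group), and a synthetic participants table (age, sex)
#' for covariate-adjusted analyses.
#'
#' @param spec a [CohortSpec-class].
#' @return a list with elements \code{recordings} (named list of
#'   [EEGRecording-class]), \code{groundTruth} (list: \code{maps},
#'   \code{labels}, \code{stats} data.frame, \code{effectSizes} data.frame,
#'   \code{participants} data.frame).
#' @examples
#' cohort <- simulateCohort(cohortSpec(c(CTRL = 2), lengthSec = 4, seed = 1))
#' names(cohort$recordings)
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  layout <- makeLayout()
  maps <- makeTemplateMaps(layout, seed = mixSeed(spec@seed, 1L))
  n <- as.integer(round(spec@lengthSec * spec@rate))
  recordings <- list()
  labelsList <- list()
  statsRows <- list()
  participants <- list()
  sub <- 0L
  for (gi in seq_len(nrow(spec@groups))) {
    gname <- spec@groups$name[gi]
    for (si in seq_len(spec@groups$n[gi])) {
      sub <- sub + 1L
      id <- sprintf("sub-%03d", sub)
      durs <- spec@meanDurationMs * spec@durationScale[gi, ]
      wts <- spec@occurrenceWeights * spec@occurrenceScale[gi, ]
      sseed <- mixSeed(spec@seed, gi, si)
      lab <- simulateLabelSequence(durs, wts, spec@rate, n, seed = sseed,
                                   gammaShape = spec@gammaShape,
                                   classNames = spec@classNames)
      rec <- renderEEG(lab, maps, rate = spec@rate, snr = spec@snr,
                       seed = mixSeed(sseed, 2L))
      st <- computeStats(lab)
      st$subject <- id
      st$group <- gname
      recordings[[id]] <- rec
      labelsList[[id]] <- lab
      statsRows[[id]] <- st
      demo <- withSeed(mixSeed(sseed, 3L), {
        list(age = round(rnorm(1L, 25, 5), 1),
             sex = sample(c("M", "F"), 1L))
      })
      participants[[id]] <- data.frame(subject = id, group = gname,
                                       age = demo$age, sex = demo$sex,
                                       stringsAsFactors = FALSE)
    }
  }
  stats <- do.call(rbind, c(statsRows, make.row.names = FALSE))
  stats <- stats[, c("subject", "group", "class", "occurrence", "coverage",
                     "meanDuration", "nRuns")]
  list(recordings = recordings,
       groundTruth = list(
         maps = maps,
         labels = labelsList,
         stats = stats,
         effectSizes = realizedEffectSizes(stats, spec@groups$name[1L]),
         participants = do.call(rbind, c(participants,
                                         make.row.names = FALSE))))
}

# Cohen's d of each group vs the reference group, per class x parameter,
# computed on the realized per-subject true statistics.
realizedEffectSizes <- function(stats, refGroup) {
  params <- c("occurrence", "coverage", "meanDuration")
  out <- list()
  for (g in setdiff(unique(stats$group), refGroup)) {
    for (cl in unique(stats$class)) {
      for (p in params) {
        x <- stats[stats$group == g & stats$class == cl, p]
        y <- stats[stats$group == refGroup & stats$class == cl, p]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        d <- if (length(x) > 1L && length(y) > 1L)
          (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2) else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          group = g, class = cl, parameter = p, cohenD = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(group = character(), class = character(),
                  parameter = character(), cohenD = numeric())
}
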
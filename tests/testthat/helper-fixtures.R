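# shared fixture builders: everything is generated in code at test time

# minimal layout with nCh channels on the unit sphere (for arithmetic toys)
toyLayout <- function(nCh = 3L) {
  th <- seq(0, pi / 3, length.out = nCh)
  pos3 <- cbind(sin(th), 0, cos(th))
  pos3 <- pos3 / sqrt(rowSums(pos3^2))
  new("SensorLayout", channels = paste0("ch", seq_len(nCh)), pos3 = pos3,
      pos2 = pos3[, 1:2, drop = FALSE])
}

# recording wrapper around a plain matrix
toyRecording <- function(data, rate = 256, layout = toyLayout(nrow(data)),
                         annotations = NULL, bads = character(),
                         reference = "native", segments = ncol(data)) {
  if (is.null(annotations))
    annotations <- data.frame(onset = numeric(), duration = numeric(),
                              label = character(), stringsAsFactors = FALSE)
  new("EEGRecording", data = data, rate = rate, layout = layout,
      annotations = annotations, bads = bads, reference = reference,
      segments = as.integer(segments), history = character())
}

# sinusoidal 19-channel recording with an eyes_closed annotation
sineRecording <- function(freq, durationSec = 20, rate = 256, amp = 10,
                          noiseSd = 0) {
  lay <- makeLayout()
  t <- seq_len(durationSec * rate) / rate
  base <- amp * sin(2 * pi * freq * t)
  gains <- seq(0.5, 1.5, length.out = 19)
  data <- outer(gains, base)
  if (noiseSd > 0) data <- data + matrix(rnorm(length(data), sd = noiseSd),
                                         nrow = 19)
  rownames(data) <- lay@channels
  toyRecording(data, rate = rate, layout = lay,
               annotations = data.frame(onset = 0, duration = durationSec,
                                        label = "eyes_closed",
                                        stringsAsFactors = FALSE))
}

# random zero-mean unit-norm peak maps on the 19-channel layout
randomPeakMaps <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * 19L), n)
    m <- m - rowMeans(m)
    m / sqrt(rowSums(m^2))
  })
}

# a small simulated single-group cohort, cached per (n, lengthSec, seed)
.cohortCache <- new.env(parent = emptyenv())
cachedCohort <- function(n = 10, lengthSec = 60, snr = 4, seed = 42) {
  key <- paste(n, lengthSec, snr, seed, sep = "_")
  if (is.null(.cohortCache[[key]])) {
    .cohortCache[[key]] <- simulateCohort(
      cohortSpec(c(CTRL = n), snr = snr, lengthSec = lengthSec, seed = seed))
  }
  .cohortCache[[key]]
}

# Cohen's d between two samples
cohenD <- function(x, y) (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2)
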
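test_that("band-pass keeps in-band sinusoids and rejects out-of-band ones", {
  rec10 <- sineRecording(10)
  out10 <- bandpass(rec10, 0.5, 40)
  core <- 257:(ncol(signalData(rec10)) - 256)   # discard 1 s edges
  ratio10 <- sd(signalData(out10)[1, core]) / sd(signalData(rec10)[1, core])
  expect_lt(abs(ratio10 - 1), 0.01)

  rec60 <- sineRecording(60)
  out60 <- bandpass(rec60, 0.5, 40)
  ratio60 <- sd(signalData(out60)[1, core]) / sd(signalData(rec60)[1, core])
  expect_lt(20 * log10(ratio60), -20)

  zeros <- toyRecording(matrix(0, 3, 2560))
  expect_equal(signalData(bandpass(zeros, 0.5, 40)),
               matrix(0, 3, 2560), tolerance = 1e-12)

  expect_error(bandpass(rec10, 30, 200), "band")
})

test_that("segment selection keeps annotated spans and their boundaries", {
  lay <- makeLayout()
  data <- matrix(rnorm(19 * 256 * 30), 19)
  ann <- data.frame(onset = c(0, 10, 20), duration = c(10, 10, 10),
                    label = c("eyes_closed", "eyes_open", "eyes_closed"),
                    stringsAsFactors = FALSE)
  rec <- toyRecording(data, layout = lay, annotations = ann)

  full <- toyRecording(data, layout = lay,
                       annotations = data.frame(onset = 0, duration = 30,
                                                label = "eyes_closed"))
  expect_identical(signalData(selectSegments(full)), data)

  sel <- selectSegments(rec)
  expect_identical(length(segmentLengths(sel)), 2L)
  expect_identical(nSamples(sel), 5120L)
  expect_identical(signalData(sel)[, 1:2560], data[, 1:2560])
  expect_identical(signalData(sel)[, 2561:5120], data[, 5121:7680])

  expect_error(selectSegments(rec, "sleep"), "no usable segment",
               class = "noUsableSegment")
})

test_that("average referencing subtracts the channel mean exactly once", {
  rec <- toyRecording(matrix(c(1, 2, 3), 3, 1))
  out <- averageReference(rec)
  expect_equal(as.numeric(signalData(out)), c(-1, 0, 1))
  expect_identical(referenceState(out), "average")

  big <- toyRecording(matrix(rnorm(3 * 100), 3))
  ref <- averageReference(big)
  expect_lte(max(abs(colMeans(signalData(ref)))), 1e-12)
  expect_error(averageReference(ref), "already")
})

test_that("single bad channels are interpolated, more cause exclusion", {
  lay <- makeLayout()
  clean <- toyRecording(matrix(rnorm(19 * 100), 19), layout = lay)
  expect_identical(signalData(interpolateBad(clean)), signalData(clean))

  const <- toyRecording(matrix(5, 19, 50), layout = lay, bads = "T3")
  fixed <- interpolateBad(const)
  expect_equal(signalData(fixed)[8, ], rep(5, 50), tolerance = 1e-6)
  expect_length(badChannels(fixed), 0L)

  two <- toyRecording(matrix(rnorm(19 * 50), 19), layout = lay,
                      bads = c("T3", "T4"))
  expect_error(interpolateBad(two), "exclude", class = "excludeRecording")
})

test_that("alpha dominance distinguishes alpha-band from theta-band rhythms", {
  set.seed(1)
  alpha <- sineRecording(10, noiseSd = 0.01)
  theta <- sineRecording(5, noiseSd = 0.01)
  expect_true(alphaDominance(alpha)$alphaDominant)
  expect_false(alphaDominance(theta)$alphaDominant)

  short <- toyRecording(matrix(rnorm(3 * 256), 3))
  expect_error(alphaDominance(short), "short")
})

test_that("a rendered subject at snr 4 passes the alpha-dominance screen", {
  rec <- cachedCohort(n = 4, lengthSec = 20, seed = 8)$recordings[[1]]
  expect_true(alphaDominance(rec)$alphaDominant)
})

test_that("segment selection after filtering is pure slicing of the filtered record", {
  lay <- makeLayout()
  data <- matrix(rnorm(19 * 256 * 12), 19)
  ann <- data.frame(onset = c(1, 8), duration = c(3, 2),
                    label = "eyes_closed", stringsAsFactors = FALSE)
  rec <- toyRecording(data, layout = lay, annotations = ann)
  filt <- bandpass(rec, 0.5, 40)
  sel <- selectSegments(filt)
  manual <- cbind(signalData(filt)[, 257:1024], signalData(filt)[, 2049:2560])
  expect_identical(signalData(sel), manual)
})

test_that("the composed preprocessing chain enforces its fixed order", {
  rec <- sineRecording(10, durationSec = 10)
  out <- preprocessRecording(rec)
  expect_identical(referenceState(out$recording), "average")
  expect_true(out$alphaDominant)
  hist <- out$recording@history
  expect_identical(hist[hist %in% c("bandpass", "select_segments",
                                    "average_reference", "interpolate")],
                   c("bandpass", "select_segments", "average_reference",
                     "interpolate"))
  expect_error(preprocessRecording(out$recording), "native")
})
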
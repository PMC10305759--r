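test_that("backfitting labels samples by maximal absolute spatial correlation", {
  tm <- makeTemplateMaps(makeLayout(), seed = 2)
  sqC <- new("MicrostateLabels", labels = rep(3L, 512), rate = 256,
             segments = 512L, classNames = c("A", "B", "C", "D"))
  rec <- renderEEG(sqC, tm, snr = Inf, seed = 1)
  lab <- backfit(rec, tm)
  expect_true(all(labelVector(lab) == 3L))
  expect_identical(classLabels(lab), c("A", "B", "C", "D"))
})

test_that("backfit agrees with per-sample correlations computed directly", {
  tm <- makeTemplateMaps(makeLayout(), seed = 3)
  X <- matrix(rnorm(19 * 200), 19)
  X <- sweep(X, 2, colMeans(X))
  rec <- toyRecording(X, layout = makeLayout(), reference = "average")
  lab <- backfit(rec, tm)
  oracle <- apply(X, 2, function(x) {
    which.max(abs(apply(mapMatrix(tm), 1, cor, y = x)))
  })
  expect_identical(labelVector(lab), as.integer(oracle))
})

test_that("backfit is invariant to polarity and positive rescaling", {
  tm <- makeTemplateMaps(makeLayout(), seed = 2)
  sq <- simulateLabelSequence(c(A = 100, B = 100, C = 100, D = 100),
                              rep(1, 4), 256, 256 * 5, seed = 6)
  rec <- renderEEG(sq, tm, snr = 4, seed = 7)
  ref <- backfit(rec, tm)
  neg <- rec; neg@data <- -neg@data
  expect_identical(labelVector(backfit(neg, tm)), labelVector(ref))
  scl <- rec; scl@data <- 42 * scl@data
  expect_identical(labelVector(backfit(scl, tm)), labelVector(ref))
})

test_that("flat samples inherit the neighbouring label", {
  tm <- makeTemplateMaps(makeLayout(), seed = 2)
  X <- t(mapMatrix(tm)[c(1, 1, 1, 2, 2), ])
  X[, 3] <- 0                      # flat sample inside an A run
  rec <- toyRecording(X, layout = makeLayout(), reference = "average")
  expect_identical(labelVector(backfit(rec, tm)), c(1L, 1L, 1L, 2L, 2L))
  Y <- t(mapMatrix(tm)[c(4, 4, 4), ])
  Y[, 1] <- 0                      # flat sample at the segment start
  rec2 <- toyRecording(Y, layout = makeLayout(), reference = "average")
  expect_identical(labelVector(backfit(rec2, tm)), c(4L, 4L, 4L))
})

test_that("temporal smoothing removes brief interruptions and fixes nothing else", {
  mk <- function(v) new("MicrostateLabels", labels = as.integer(v),
                        rate = 256, segments = length(v),
                        classNames = c("A", "B", "C", "D"))
  # a 2-sample D interruption inside class C vanishes (82 ms -> 21 samples)
  seq1 <- mk(c(rep(3, 30), rep(4, 2), rep(3, 30)))
  expect_true(all(labelVector(smoothLabels(seq1, 82)) == 3L))
  # constant sequences are fixed points
  seq2 <- mk(rep(2, 100))
  expect_identical(labelVector(smoothLabels(seq2, 82)), rep(2L, 100))
  # sample count conserved, no class invented
  seq3 <- mk(withr::with_seed(4, sample(1:3, 400, replace = TRUE)))
  sm <- smoothLabels(seq3, 82)
  expect_identical(nSamples(sm), 400L)
  expect_true(all(labelVector(sm) %in% 1:3))
  # window must fit the shortest segment
  seq4 <- new("MicrostateLabels", labels = rep(1L, 40), rate = 256,
              segments = c(30L, 10L), classNames = "A")
  expect_error(smoothLabels(seq4, 82), "segment")
})

test_that("smoothing uses the documented window arithmetic", {
  # 82 ms at 256 Hz is a 21-sample full window
  expect_identical(as.integer(round(82 * 256 / 1000)), 21L)
  # a 10-sample interruption (< ceiling(21/2)) is removed between long runs
  mk <- function(v) new("MicrostateLabels", labels = as.integer(v),
                        rate = 256, segments = length(v),
                        classNames = c("A", "B", "C", "D"))
  seq <- mk(c(rep(1, 40), rep(2, 10), rep(1, 40)))
  expect_true(all(labelVector(smoothLabels(seq, 82)) == 1L))
  # a run longer than the half window survives
  seq2 <- mk(c(rep(1, 40), rep(2, 15), rep(1, 40)))
  expect_true(any(labelVector(smoothLabels(seq2, 82)) == 2L))
})

test_that("per-class statistics match hand-enumerated runs", {
  sq <- new("MicrostateLabels",
            labels = as.integer(c(rep(1, 6), rep(2, 4), rep(1, 6), rep(3, 4))),
            rate = 10, segments = 20L,
            classNames = c("A", "B", "C", "D"))
  st <- computeStats(sq)
  expect_equal(st$occurrence, c(1.0, 0.5, 0.5, 0))
  expect_equal(st$coverage, c(60, 20, 20, 0))
  expect_equal(st$meanDuration, c(600, 400, 400, NA_real_))
  expect_identical(st$nRuns, c(2L, 1L, 1L, 0L))
  expect_equal(attr(st, "totalTime"), 2)
})

test_that("degenerate and spliced label sequences are counted correctly", {
  solo <- new("MicrostateLabels", labels = rep(2L, 50), rate = 10,
              segments = 50L, classNames = c("A", "B"))
  st <- computeStats(solo)
  expect_equal(st$coverage[2], 100)
  expect_equal(st$occurrence[2], 1 / 5)
  # a run never crosses a splice
  spliced <- new("MicrostateLabels", labels = rep(1L, 40), rate = 10,
                 segments = c(20L, 20L), classNames = "A")
  expect_identical(computeStats(spliced)$nRuns, 2L)
  expect_equal(computeStats(spliced)$meanDuration, 2000)
})

test_that("coverage and occurrence-duration identities hold for random sequences", {
  for (seed in 1:25) {
    K <- withr::with_seed(seed, sample(2:6, 1))
    sq <- simulateLabelSequence(
      stats::setNames(withr::with_seed(seed + 1, runif(K, 40, 200)),
                      LETTERS[1:K]),
      withr::with_seed(seed + 2, runif(K, 0.2, 1)),
      rate = 256, nSamples = 2000, seed = seed)
    st <- computeStats(sq)
    expect_equal(sum(st$coverage), 100, tolerance = 1e-9)
    ok <- st$nRuns > 0
    expect_equal(st$occurrence[ok] * st$meanDuration[ok] / 1000,
                 st$coverage[ok] / 100, tolerance = 1e-9)
  }
})

test_that("C/D ratios follow their definition and flag missing denominators", {
  st <- data.frame(class = c("C", "D"),
                   occurrence = c(2, 2), coverage = c(30, 20),
                   meanDuration = c(100, 100))
  r <- cdRatios(st)
  expect_equal(r$ratio[r$parameter == "occurrence"], 1)
  expect_equal(r$ratio[r$parameter == "coverage"], 1.5)
  stD0 <- data.frame(class = c("C", "D"), occurrence = c(2, 0),
                     coverage = c(30, 0), meanDuration = c(100, NA))
  expect_warning(r0 <- cdRatios(stD0), "denominator")
  expect_true(all(is.na(r0$ratio)))
})

test_that("noiseless backfit reproduces ground-truth statistics", {
  cohort <- simulateCohort(cohortSpec(c(CTRL = 2), snr = Inf, lengthSec = 30,
                                      seed = 21))
  tm <- cohort$groundTruth$maps
  for (id in names(cohort$recordings)) {
    st <- computeStats(backfit(cohort$recordings[[id]], tm))
    tr <- cohort$groundTruth$stats
    tr <- tr[tr$subject == id, ]
    expect_lte(max(abs(st$coverage - tr$coverage)), 2)
    expect_lte(max(abs(st$meanDuration / tr$meanDuration - 1), na.rm = TRUE),
               0.10)
  }
})
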
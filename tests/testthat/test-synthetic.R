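test_that("template maps are canonical: normalized, mutually distinct, seed-stable", {
  lay <- makeLayout()
  for (seed in c(1L, 2L, 7L)) {
    tm <- makeTemplateMaps(lay, seed = seed)
    M <- mapMatrix(tm)
    expect_identical(nMaps(tm), 4L)
    expect_true(all(abs(rowMeans(M)) <= 1e-12))
    expect_true(all(abs(sqrt(rowSums(M^2)) - 1) <= 1e-12))
    cc <- abs(cor(t(M)))
    diag(cc) <- 0
    expect_lte(max(cc), 0.7)
  }
  expect_identical(mapMatrix(makeTemplateMaps(lay, seed = 3L)),
                   mapMatrix(makeTemplateMaps(lay, seed = 3L)))
})

test_that("label sequences hit their target sojourn statistics", {
  sq <- simulateLabelSequence(c(A = 100, B = 100, C = 100, D = 100),
                              rep(1, 4), rate = 256, nSamples = 256000,
                              seed = 7)
  st <- computeStats(sq)
  grand <- with(st, sum(meanDuration * nRuns) / sum(nRuns))
  expect_lt(abs(grand - 100) / 100, 0.10)
  # per-class sojourn means converge (every class has >> 500 runs here)
  expect_true(all(st$nRuns > 500))
  expect_true(all(abs(st$meanDuration - 100) / 100 < 0.05))
})

test_that("label sequence degenerate cases and input validation", {
  one <- simulateLabelSequence(c(A = 100), 1, rate = 256, nSamples = 500,
                               seed = 1)
  expect_true(all(labelVector(one) == 1L))
  single <- simulateLabelSequence(c(A = 80, B = 120), c(1, 1), rate = 256,
                                  nSamples = 1, seed = 1)
  expect_identical(nSamples(single), 1L)
  expect_error(simulateLabelSequence(c(A = 100, B = 100), c(0, 0), 256, 10),
               "weights")
  expect_error(simulateLabelSequence(c(A = -5, B = 100), c(1, 1), 256, 10),
               "positive")
})

test_that("rendered EEG is average-referenced and proportional to the active map when noiseless", {
  lay <- makeLayout()
  tm <- makeTemplateMaps(lay, seed = 2)
  sq <- simulateLabelSequence(c(A = 100, B = 100, C = 100, D = 100),
                              rep(1, 4), 256, 256 * 4, seed = 5)
  rec <- renderEEG(sq, tm, snr = Inf, seed = 9)
  expect_identical(referenceState(rec), "average")
  X <- signalData(rec)
  expect_lte(max(abs(colMeans(X))), 1e-9)
  lv <- labelVector(sq)
  nrm <- sqrt(colSums(X^2))
  probe <- which(nrm > 0.1 * max(nrm))[1:50]
  for (t in probe) {
    expect_equal(abs(cor(X[, t], mapMatrix(tm)[lv[t], ])), 1,
                 tolerance = 1e-9)
  }
})

test_that("rendered EEG with noise keeps alpha-band dominance", {
  tm <- makeTemplateMaps(makeLayout(), seed = 2)
  sq <- simulateLabelSequence(c(A = 100, B = 100, C = 100, D = 100),
                              rep(1, 4), 256, 256 * 60, seed = 11)
  rec <- renderEEG(sq, tm, snr = 4, seed = 3)
  expect_lte(max(abs(colMeans(signalData(rec)))), 1e-9)
  rep <- alphaDominance(rec)
  expect_gt(rep$bandPower[["alpha"]], rep$bandPower[["beta"]])
  expect_true(rep$alphaDominant)
})

test_that("renderEEG validates its inputs", {
  tm <- makeTemplateMaps(makeLayout(), seed = 2)
  sq3 <- new("MicrostateLabels", labels = rep(1L, 100), rate = 256,
             segments = 100L, classNames = c("A", "B", "C"))
  expect_error(renderEEG(sq3, tm), "number of classes")
  sq <- simulateLabelSequence(c(A = 100, B = 100, C = 100, D = 100),
                              rep(1, 4), 256, 100, seed = 1)
  expect_error(renderEEG(sq, tm, snr = 0), "snr")
})

test_that("simulated cohorts satisfy the coverage and occurrence-duration identities", {
  cohort <- cachedCohort(n = 4, lengthSec = 20, seed = 8)
  st <- cohort$groundTruth$stats
  for (id in unique(st$subject)) {
    s <- st[st$subject == id, ]
    expect_equal(sum(s$coverage), 100, tolerance = 1e-9)
    ok <- !is.na(s$meanDuration)
    expect_equal(s$occurrence[ok] * s$meanDuration[ok] / 1000,
                 s$coverage[ok] / 100, tolerance = 1e-9)
  }
})

test_that("same seed and spec give a bit-identical cohort", {
  spec <- cohortSpec(c(CTRL = 2), lengthSec = 5, seed = 31)
  a <- simulateCohort(spec)
  b <- simulateCohort(spec)
  expect_identical(signalData(a$recordings[[1]]), signalData(b$recordings[[1]]))
  expect_identical(a$groundTruth$stats, b$groundTruth$stats)
})

test_that("group perturbations shape realized effect sizes as requested", {
  # identical parameters: class-D duration effect is sampling noise only
  null <- simulateCohort(cohortSpec(c(CTRL = 10, OTH = 10), lengthSec = 30,
                                    seed = 1))
  dNull <- subset(null$groundTruth$effectSizes,
                  class == "D" & parameter == "meanDuration")$cohenD
  expect_lt(abs(dNull), 0.8)
  # 40% class-D sojourn reduction: realized effect is negative
  dis <- simulateCohort(cohortSpec(c(CTRL = 8, DIS = 8), lengthSec = 30,
                                   durationScale = list(DIS = c(D = 0.6)),
                                   seed = 2))
  dDis <- subset(dis$groundTruth$effectSizes,
                 class == "D" & parameter == "meanDuration")$cohenD
  expect_lt(dDis, 0)
  # boundary: n = 1 per group
  tiny <- simulateCohort(cohortSpec(c(A = 1, B = 1), lengthSec = 5, seed = 3))
  expect_length(tiny$recordings, 2L)
  expect_identical(length(unique(tiny$groundTruth$stats$subject)), 2L)
})
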
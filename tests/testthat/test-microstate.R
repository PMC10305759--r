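test_that("GFP is the population spatial SD and scales homogeneously", {
  rec <- toyRecording(matrix(c(1, -1), 2, 1), layout = toyLayout(2),
                      reference = "average")
  expect_equal(gfpValues(gfp(rec)), 1.0)

  zero <- toyRecording(matrix(0, 2, 3), layout = toyLayout(2),
                       reference = "average")
  expect_equal(gfpValues(gfp(zero)), rep(0, 3))

  v <- matrix(rnorm(4 * 10), 4)
  v <- sweep(v, 2, colMeans(v))
  base <- toyRecording(v, layout = toyLayout(4), reference = "average")
  scaled <- toyRecording(3.7 * v, layout = toyLayout(4), reference = "average")
  expect_equal(gfpValues(gfp(scaled)), 3.7 * gfpValues(gfp(base)),
               tolerance = 1e-12)

  native <- toyRecording(v, layout = toyLayout(4))
  expect_error(gfp(native), "average-referenced")
})

test_that("GFP peaks are strict per-segment local maxima", {
  s <- new("GFPSeries", values = c(0, 1, 0, 2, 0), rate = 10, segments = 5L)
  expect_identical(gfpPeaks(s), c(2L, 4L))

  mono <- new("GFPSeries", values = 1:10 / 10, rate = 10, segments = 10L)
  expect_identical(gfpPeaks(mono), integer())

  # a maximum at a segment edge is not a peak
  spliced <- new("GFPSeries", values = c(1, 2, 3, 2, 1), rate = 10,
                 segments = c(3L, 2L))
  expect_identical(gfpPeaks(spliced), integer())
  whole <- new("GFPSeries", values = c(1, 2, 3, 2, 1), rate = 10,
               segments = 5L)
  expect_identical(gfpPeaks(whole), 3L)
})

test_that("a noiseless alpha rendering yields about two GFP peaks per cycle", {
  tm <- makeTemplateMaps(makeLayout(), seed = 2)
  sq <- simulateLabelSequence(c(A = 100, B = 100, C = 100, D = 100),
                              rep(1, 4), 256, 256 * 10, seed = 4)
  rec <- renderEEG(sq, tm, snr = Inf, seed = 6)
  rate <- length(gfpPeaks(gfp(rec))) / 10
  expect_gt(rate, 20 * 0.8)
  expect_lt(rate, 20 * 1.2)
})

test_that("modified K-means recovers orthogonal generating maps exactly", {
  tm <- mapMatrix(makeTemplateMaps(makeLayout(), seed = 3))
  # orthogonalize the first two templates
  m1 <- tm[1, ]
  m2 <- tm[2, ] - sum(tm[2, ] * m1) * m1
  m2 <- m2 - mean(m2)
  m2 <- m2 / sqrt(sum(m2^2))
  truth <- rbind(m1, m2)
  signs <- rep(c(1, -1), 20)
  peaks <- truth[rep(1:2, each = 20), ] * signs
  fit <- modifiedKmeans(peaks, K = 2, seed = 1)
  r <- spatialCorrelationMatrix(mapMatrix(fit), truth)
  best <- apply(r, 1, max)
  expect_true(all(best > 1 - 1e-6))
  expect_equal(gev(fit), 1, tolerance = 1e-9)
})

test_that("modified K-means is polarity-invariant and its GEV trace is monotone", {
  peaks <- randomPeakMaps(60, seed = 5)
  fit <- modifiedKmeans(peaks, K = 3, seed = 2)
  expect_true(all(diff(fit@gevTrace) >= -1e-12))

  flip <- withr::with_seed(8, sample(c(-1, 1), 60, replace = TRUE))
  fitF <- modifiedKmeans(peaks * flip, K = 3, seed = 2)
  expect_equal(mapMatrix(fitF), mapMatrix(fit), tolerance = 1e-9)
  expect_equal(gev(fitF), gev(fit), tolerance = 1e-12)
})

test_that("modified K-means GEV equals the exhaustive-assignment optimum on small inputs", {
  # independent oracle: enumerate every 2-cluster assignment of <= 8 peaks,
  # fit each cluster's optimal map in closed form, and take the best GEV
  exhaustiveGev <- function(X, w, K = 2) {
    n <- nrow(X)
    w <- w / sum(w)
    best <- -Inf
    for (code in 0:(2^n - 1)) {
      a <- as.integer(intToBits(code))[1:n] + 1L
      if (length(unique(a)) < K) next
      gev <- 0
      for (k in 1:K) {
        members <- which(a == k)
        S <- crossprod(X[members, , drop = FALSE] * sqrt(w[members]))
        e <- eigen(S, symmetric = TRUE)
        v <- e$vectors[, 1]
        v <- v - mean(v)
        v <- v / sqrt(sum(v^2))
        gev <- gev + sum(w[members] * (X[members, , drop = FALSE] %*% v)^2)
      }
      best <- max(best, gev)
    }
    best
  }
  for (seed in 1:3) {
    X <- randomPeakMaps(8, seed = seed)
    w <- withr::with_seed(seed + 50, runif(8, 0.5, 2))
    fit <- modifiedKmeans(X, K = 2, gfpWeights = w, nInit = 20, seed = 1)
    expect_equal(gev(fit), exhaustiveGev(X, w^2), tolerance = 1e-9)
  }
})

test_that("silhouette matches its direct definition and picks the generating K", {
  # two coincident points and one at distance 1: s = (1, 1, 0)
  D <- matrix(c(0, 0, 1,
                0, 0, 1,
                1, 1, 0), 3, byrow = TRUE)
  expect_equal(microstates:::meanSilhouette(D, c(1L, 1L, 2L), 2L), 2 / 3)

  truth <- mapMatrix(makeTemplateMaps(makeLayout(), seed = 4))
  peaks <- truth[rep(1:4, each = 30), ] +
    0.1 * randomPeakMaps(120, seed = 9)
  sil <- silhouetteK(peaks, kRange = 2:6, seed = 1)
  expect_identical(sil$bestK, 4L)
  expect_gte(sil$scores[["4"]], sil$scores[["5"]])
})

test_that("spatial correlation is polarity-invariant and detects orthogonality", {
  a <- randomPeakMaps(1, seed = 1)[1, ]
  expect_equal(spatialCorrelation(a, a), 1.0)
  expect_equal(spatialCorrelation(a, -a), 1.0)
  b <- randomPeakMaps(1, seed = 2)[1, ]
  bPerp <- b - sum(a * b) / sum(a * a) * a
  bPerp <- bPerp - mean(bPerp)
  # re-orthogonalize after centering (centering of a zero-mean a keeps it)
  bPerp <- bPerp - sum(a * bPerp) / sum(a * a) * a
  expect_lt(spatialCorrelation(a, bPerp), 1e-9)
  expect_error(spatialCorrelation(a, rep(1, 19)), "zero-variance")
})

test_that("map labeling recovers permutations and matches brute force", {
  ref <- makeTemplateMaps(makeLayout(), seed = 5)
  lab <- labelMaps(ref, ref)
  expect_identical(lab@metadata$assignment, 1:4)
  expect_equal(unname(lab@metadata$referenceCorrelation), rep(1, 4),
               tolerance = 1e-12)

  perm <- c(3L, 1L, 4L, 2L)
  shuffled <- ref
  shuffled@maps <- ref@maps[perm, ]
  shuffled@classLabels <- rep(NA_character_, 4)
  out <- labelMaps(shuffled, ref)
  expect_identical(classLabels(out), c("A", "B", "C", "D"))
  expect_equal(mapMatrix(out), mapMatrix(ref), tolerance = 1e-12)

  # brute-force oracle over all K! permutations of random score matrices
  allPerms <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (sub in allPerms(n - 1)) {
      for (pos in 0:(n - 1)) {
        out[[length(out) + 1L]] <- append(sub, n, after = pos)
      }
    }
    out
  }
  bruteBest <- function(S) {
    max(vapply(allPerms(nrow(S)), function(p) {
      sum(S[cbind(seq_len(nrow(S)), p)])
    }, numeric(1)))
  }
  for (seed in 1:10) {
    n <- if (seed %% 2 == 0) 4L else 5L
    S <- withr::with_seed(seed, matrix(runif(n * n), n))
    perm <- microstates:::hungarianMax(S)
    expect_equal(sum(S[cbind(seq_len(n), perm)]), bruteBest(S),
                 tolerance = 1e-12)
  }
})

test_that("two-level clustering of one subject reproduces that subject's maps", {
  rec <- cachedCohort(n = 4, lengthSec = 20, seed = 8)$recordings[[2]]
  pk <- peakTopographies(rec)
  solo <- modifiedKmeans(pk$maps, K = 4, gfpWeights = pk$gfp,
                         seed = microstates:::mixSeed(1L, 41L, 1L))
  grp <- twoLevelCluster(list(rec), K = 4, seed = 1L)
  r <- spatialCorrelationMatrix(grp, mapMatrix(solo))
  expect_true(all(apply(r, 1, max) > 1 - 1e-6))
  expect_error(twoLevelCluster(list(), K = 4), "at least one")
})

test_that("clustering is invariant to positive rescaling of the recording", {
  rec <- cachedCohort(n = 4, lengthSec = 20, seed = 8)$recordings[[3]]
  scaled <- rec
  scaled@data <- 2.5 * scaled@data
  a <- twoLevelCluster(list(rec), K = 4, seed = 3L)
  b <- twoLevelCluster(list(scaled), K = 4, seed = 3L)
  expect_equal(mapMatrix(a), mapMatrix(b), tolerance = 1e-9)
})
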
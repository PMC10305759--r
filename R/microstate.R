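#' Global field power of an average-referenced recording
#'
#' GFP at each sample is the spatial standard deviation of the scalp
#' potential across electrodes (population form: the sum of squares is
#' divided by the channel count; with an average-referenced signal the
#' spatial mean is zero so this is the root-mean-square over channels).
#'
#' @param rec an average-referenced [EEGRecording-class].
#' @return a [GFPSeries-class].
#' @export
gfp <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@reference != "average")
    stop("GFP requires an average-referenced recording")
  centered <- sweep(rec@data, 2L, colMeans(rec@data))
  new("GFPSeries", values = sqrt(colMeans(centered^2)), rate = rec@rate,
      segments = rec@segments)
}

#' Indices of GFP peaks
#'
#' Strict local maxima of the GFP series, computed within each contiguous
#' segment so a peak is never detected across a splice between
#' non-contiguous spans. Returned ascending.
#'
#' @param series a [GFPSeries-class].
#' @return integer vector of peak sample indices (possibly empty).
#' @export
gfpPeaks <- function(series) {
  stopifnot(is(series, "GFPSeries"))
  v <- series@values
  starts <- segmentStarts(series@segments)
  out <- integer()
  for (s in seq_along(starts)) {
    a <- starts[s]
    b <- a + series@segments[s] - 1L
    if (b - a < 2L) next
    i <- (a + 1L):(b - 1L)
    hit <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
    out <- c(out, i[hit])
  }
  out
}

#' Extract topographies at GFP peaks
#'
#' Returns the instantaneous scalp maps at GFP-peak samples, normalized to
#' zero mean and unit norm per map, together with the original GFP value of
#' each peak (used as clustering weight: the global explained variance
#' weights each peak by its squared GFP).
#'
#' @param rec an average-referenced [EEGRecording-class].
#' @param series optional precomputed [GFPSeries-class].
#' @return list: \code{maps} (peaks x channels, normalized), \code{gfp}
#'   (numeric), \code{index} (sample indices).
#' @export
peakTopographies <- function(rec, series = gfp(rec)) {
  idx <- gfpPeaks(series)
  if (!length(idx)) stop("no GFP peaks found")
  m <- t(rec@data[, idx, drop = FALSE])
  m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  keep <- nrm > 0
  list(maps = m[keep, , drop = FALSE] / nrm[keep],
       gfp = series@values[idx][keep], index = idx[keep])
}

# deterministic sign convention: the channel with the largest |loading|
# is positive
canonicalSign <- function(M) {
  s <- vapply(seq_len(nrow(M)), function(i) {
    sign(M[i, which.max(abs(M[i, ]))])
  }, numeric(1))
  s[s == 0] <- 1
  M * s
}

#' Polarity-invariant modified K-means clustering of topographies
#'
#' The microstate variant of K-means: a peak map is assigned to the cluster
#' whose map has the highest squared spatial (Pearson) correlation with it
#' — squared, so opposite-polarity maps belong together — and each
#' cluster's map is updated as the first principal eigenvector of the
#' GFP^2-weighted outer-product sum of its members (the sign-free
#' maximizer of the cluster's explained variance), renormalized to zero
#' mean and unit norm. The objective is the global explained variance
#' \deqn{GEV = \sum_p GFP_p^2 r^2_{p,assigned} / \sum_p GFP_p^2,}
#' which is non-decreasing over iterations; iteration stops when the GEV
#' improvement falls below \code{tol} or after \code{maxIter} iterations.
#' The best of \code{nInit} random restarts is returned. An emptied cluster
#' is reseeded with the peak currently worst explained by its assigned map.
#'
#' @param peakMaps numeric matrix, peaks x channels (rows need not be
#'   normalized; they are centered and scaled internally).
#' @param K number of clusters.
#' @param gfpWeights optional per-peak GFP values; defaults to the row
#'   norms of \code{peakMaps} before normalization (equal weights if the
#'   rows are already unit-norm).
#' @param nInit random restarts (default 10).
#' @param maxIter iteration cap per restart (default 100).
#' @param tol convergence tolerance on the GEV (default 1e-6).
#' @param seed integer seed.
#' @param channels optional channel names for the fitted maps.
#' @return a [ClusterFit-class].
#' @export
modifiedKmeans <- function(peakMaps, K, gfpWeights = NULL, nInit = 10,
                           maxIter = 100, tol = 1e-6, seed = 1L,
                           channels = NULL) {
  peakMaps <- as.matrix(peakMaps)
  n <- nrow(peakMaps)
  if (K < 1L) stop("K must be >= 1")
  if (n < K) stop("need at least K peak maps")
  if (is.null(gfpWeights)) {
    ctr <- peakMaps - rowMeans(peakMaps)
    gfpWeights <- sqrt(rowMeans(ctr^2))
    if (all(abs(gfpWeights - gfpWeights[1L]) < 1e-12))
      gfpWeights <- rep(1, n)
  }
  X <- peakMaps - rowMeans(peakMaps)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("zero-variance peak map")
  X <- X / nrm
  w <- gfpWeights^2
  w <- w / sum(w)
  if (is.null(channels)) {
    channels <- colnames(peakMaps)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(X)))
  }

  best <- NULL
  seeds <- vapply(seq_len(nInit), function(i) mixSeed(seed, 31L, i), integer(1))
  for (init in seq_len(nInit)) {
    fit <- withSeed(seeds[init], {
      runModifiedKmeansOnce(X, w, K, maxIter, tol)
    })
    if (is.null(best) || fit$gev > best$gev) best <- fit
  }
  maps <- canonicalSign(best$maps)
  colnames(maps) <- channels
  rownames(maps) <- NULL
  new("ClusterFit",
      mapset = new("MicrostateMaps", maps = maps,
                   classLabels = rep(NA_character_, K), channels = channels,
                   provenance = "modified-kmeans", metadata = list()),
      assignments = best$assign, gev = best$gev, gevTrace = best$trace,
      nIter = length(best$trace), converged = best$converged)
}

# one restart of the modified K-means on normalized rows X with weights w
runModifiedKmeansOnce <- function(X, w, K, maxIter, tol) {
  n <- nrow(X)
  maps <- X[sample.int(n, K), , drop = FALSE]
  gevOld <- -Inf
  trace <- numeric()
  converged <- FALSE
  assign <- integer(n)
  for (it in seq_len(maxIter)) {
    corr <- X %*% t(maps)           # rows and maps zero-mean unit-norm
    r2 <- corr^2
    assign <- max.col(r2, ties.method = "first")
    # reseed empty clusters with the worst-explained peak
    rA <- r2[cbind(seq_len(n), assign)]
    for (k in seq_len(K)) {
      if (!any(assign == k)) {
        worst <- which.min(rA)
        assign[worst] <- k
        maps[k, ] <- X[worst, ]
        rA[worst] <- 1
      }
    }
    # update: principal eigenvector of the weighted outer-product sum
    for (k in seq_len(K)) {
      members <- which(assign == k)
      S <- crossprod(X[members, , drop = FALSE] * sqrt(w[members]))
      v <- eigen(S, symmetric = TRUE)$vectors[, 1L]
      v <- v - mean(v)
      maps[k, ] <- v / sqrt(sum(v^2))
    }
    corr <- X %*% t(maps)
    r2 <- corr^2
    assign <- max.col(r2, ties.method = "first")
    gevNew <- sum(w * r2[cbind(seq_len(n), assign)])
    trace <- c(trace, gevNew)
    if (gevNew - gevOld < tol && it > 1L) {
      converged <- TRUE
      gevOld <- max(gevOld, gevNew)
      break
    }
    gevOld <- gevNew
  }
  list(maps = maps, assign = assign, gev = gevOld, trace = trace,
       converged = converged)
}

#' Choose the number of microstate maps by silhouette
#'
#' Fits the modified K-means for each candidate K and scores it with the
#' mean silhouette over peaks, using the polarity-invariant distance
#' d(x, y) = 1 - |corr(x, y)|. For large peak sets the silhouette is
#' evaluated on a deterministic subsample (default cap 2000 peaks) since
#' the pairwise distance matrix is quadratic in the peak count.
#'
#' @param peakMaps numeric matrix, peaks x channels.
#' @param kRange integer vector of candidate K (must lie in
#'   [2, nPeaks - 1]).
#' @param gfpWeights optional per-peak GFP values (passed to the fits).
#' @param seed integer seed.
#' @param maxPoints silhouette subsample cap.
#' @param ... further arguments to [modifiedKmeans()].
#' @return list: \code{bestK}, \code{scores} (named numeric per K),
#'   \code{fits} (list of [ClusterFit-class]).
#' @export
silhouetteK <- function(peakMaps, kRange = 2:7, gfpWeights = NULL, seed = 1L,
                        maxPoints = 2000L, ...) {
  peakMaps <- as.matrix(peakMaps)
  n <- nrow(peakMaps)
  if (any(kRange < 2L) || any(kRange > n - 1L))
    stop("kRange must lie within [2, nPeaks - 1]")
  X <- peakMaps - rowMeans(peakMaps)
  X <- X / sqrt(rowSums(X^2))
  sub <- if (n > maxPoints) {
    withSeed(mixSeed(seed, 77L), sort(sample.int(n, maxPoints)))
  } else seq_len(n)
  D <- 1 - abs(tcrossprod(X[sub, , drop = FALSE]))
  D[D < 0] <- 0
  scores <- numeric(length(kRange))
  names(scores) <- as.character(kRange)
  fits <- list()
  for (i in seq_along(kRange)) {
    K <- kRange[i]
    fit <- modifiedKmeans(peakMaps, K, gfpWeights = gfpWeights,
                          seed = mixSeed(seed, 13L, K), ...)
    scores[i] <- meanSilhouette(D, fit@assignments[sub], K)
    fits[[as.character(K)]] <- fit
  }
  list(bestK = kRange[which.max(scores)], scores = scores, fits = fits)
}

# mean silhouette from a precomputed distance matrix and hard assignments
meanSilhouette <- function(D, assign, K) {
  n <- nrow(D)
  ind <- matrix(0, n, K)
  ind[cbind(seq_len(n), assign)] <- 1
  counts <- colSums(ind)
  sums <- D %*% ind                    # n x K: total distance to each cluster
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- assign[i]
    if (counts[k] <= 1L) { s[i] <- 0; next }
    a <- sums[i, k] / (counts[k] - 1L)
    others <- which(counts > 0)
    others <- others[others != k]
    if (!length(others)) { s[i] <- 0; next }
    b <- min(sums[i, others] / counts[others])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Two-level (subject then group) microstate clustering
#'
#' First level: for each subject, GFP peaks are extracted and clustered
#' into K maps with the modified K-means. Second level: all subjects'
#' fitted maps are concatenated (with equal weights, since the first level
#' has already absorbed the GFP weighting) and clustered again into K
#' group-level maps.
#'
#' @param recordings list of average-referenced [EEGRecording-class].
#' @param K number of maps.
#' @param seed integer seed.
#' @param groupName provenance tag for the returned set.
#' @param ... further arguments to [modifiedKmeans()].
#' @return a [MicrostateMaps-class] with provenance "group:<groupName>" and
#'   the per-subject fits in \code{metadata$subjectFits}.
#' @export
twoLevelCluster <- function(recordings, K = 4, seed = 1L,
                            groupName = "group", ...) {
  if (!length(recordings)) stop("need at least one recording")
  subjectMaps <- vector("list", length(recordings))
  fits <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    pk <- peakTopographies(recordings[[i]])
    fit <- modifiedKmeans(pk$maps, K, gfpWeights = pk$gfp,
                          seed = mixSeed(seed, 41L, i), ...)
    subjectMaps[[i]] <- mapMatrix(fit)
    fits[[i]] <- fit
  }
  pool <- do.call(rbind, subjectMaps)
  groupFit <- modifiedKmeans(pool, K, gfpWeights = rep(1, nrow(pool)),
                             seed = mixSeed(seed, 43L), ...)
  ms <- groupFit@mapset
  ms@provenance <- paste0("group:", groupName)
  ms@metadata <- list(subjectFits = fits, groupFit = groupFit)
  ms
}

#' Absolute spatial correlation between two topographies
#'
#' The polarity-invariant similarity used throughout microstate analysis:
#' the absolute Pearson correlation across channels.
#'
#' @param a,b numeric vectors over the same channels.
#' @return a number in [0, 1].
#' @export
spatialCorrelation <- function(a, b) {
  if (length(a) != length(b)) stop("maps must share the channel count")
  if (sd(a) == 0 || sd(b) == 0) stop("zero-variance map")
  abs(cor(a, b))
}

#' Matrix of absolute spatial correlations between two map sets
#'
#' @param a,b [MicrostateMaps-class] objects (or plain K x channels
#'   matrices) on the same channels.
#' @return |correlation| matrix, rows indexing \code{a}, columns \code{b}.
#' @export
spatialCorrelationMatrix <- function(a, b) {
  A <- if (is(a, "MicrostateMaps")) a@maps else as.matrix(a)
  B <- if (is(b, "MicrostateMaps")) b@maps else as.matrix(b)
  if (ncol(A) != ncol(B)) stop("map sets must share the channel count")
  ctr <- function(M) {
    M <- M - rowMeans(M)
    M / sqrt(rowSums(M^2))
  }
  abs(tcrossprod(ctr(A), ctr(B)))
}

#' Label a map set against a labelled reference set
#'
#' Finds the one-to-one assignment of maps to reference classes that
#' maximizes the total absolute spatial correlation (optimal bipartite
#' matching via the Hungarian algorithm), reorders the maps into the
#' reference class order, aligns their polarity with the reference, and
#' reports the per-class correlations (the ingredients of a
#' group-vs-control correlation matrix).
#'
#' @param maps an unlabelled [MicrostateMaps-class].
#' @param reference a labelled [MicrostateMaps-class] with the same K and
#'   channels.
#' @return the relabelled [MicrostateMaps-class]; per-class correlations in
#'   \code{metadata$referenceCorrelation}, the permutation in
#'   \code{metadata$assignment}, and the full correlation matrix in
#'   \code{metadata$correlationMatrix}.
#' @export
labelMaps <- function(maps, reference) {
  stopifnot(is(maps, "MicrostateMaps"), is(reference, "MicrostateMaps"))
  if (nMaps(maps) != nMaps(reference))
    stop("map sets must have the same K")
  if (nChannels(maps) != nChannels(reference))
    stop("map sets must share the channel count")
  R <- spatialCorrelationMatrix(reference, maps)  # ref x candidate
  perm <- hungarianMax(R)                          # candidate index per ref row
  ordered <- maps@maps[perm, , drop = FALSE]
  # align polarity with the reference
  for (i in seq_len(nrow(ordered))) {
    if (cor(ordered[i, ], reference@maps[i, ]) < 0)
      ordered[i, ] <- -ordered[i, ]
  }
  out <- maps
  out@maps <- ordered
  out@classLabels <- reference@classLabels
  out@metadata <- c(maps@metadata, list(
    referenceCorrelation = stats::setNames(R[cbind(seq_len(nrow(R)), perm)],
                                           reference@classLabels),
    assignment = perm,
    correlationMatrix = R))
  out
}

# Hungarian algorithm (shortest augmenting path with potentials) on a
# square score matrix; returns, per row, the column maximizing total score.
hungarianMax <- function(S) {
  n <- nrow(S)
  stopifnot(ncol(S) == n)
  C <- max(S) - S   # convert to minimization
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j]: row assigned to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L            # columns are offset by 1 (index 1 = virtual)
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (used[j]) next
        cur <- C[i0, j - 1L] - u[i0 + 0L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in 2L:(n + 1L)) perm[p[j]] <- j - 1L
  perm
}
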
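#' Highest density interval of a sample of draws
#'
#' Shortest contiguous interval containing the requested posterior mass,
#' by the sorted-window method: among all windows of \code{ceil(mass * n)}
#' consecutive order statistics, the narrowest one.
#'
#' @param draws numeric vector of posterior draws (n >= 10).
#' @param mass probability mass in (0, 1), default 0.90.
#' @return numeric length-2: lower and upper HDI bound.
#' @examples
#' hdi(stats::qnorm(seq(0.0005, 0.9995, length.out = 2000)), 0.9)
#' @export
hdi <- function(draws, mass = 0.90) {
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 10L) stop("need at least 10 draws for an HDI")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1L], x[n]))
  width <- x[(m + 1L):n] - x[seq_len(n - m)]
  i <- which.min(width)
  c(x[i], x[i + m])
}

# the robust two-group t model (shared normality parameter, per-group mean
# and scale), with the reference broad data-scaled priors
bestModelString <- "
model {
  for (i in 1:Nx) { x[i] ~ dt(mu1, tau1, nu) }
  for (j in 1:Ny) { y[j] ~ dt(mu2, tau2, nu) }
  mu1 ~ dnorm(muM, muP)
  mu2 ~ dnorm(muM, muP)
  sigma1 ~ dunif(sigmaLo, sigmaHi)
  sigma2 ~ dunif(sigmaLo, sigmaHi)
  tau1 <- pow(sigma1, -2)
  tau2 <- pow(sigma2, -2)
  nuMinusOne ~ dexp(nuRate)
  nu <- nuMinusOne + 1
}
"

#' Robust Bayesian two-group comparison with a ROPE decision
#'
#' Bayesian estimation of a two-group difference with t-distributed
#' likelihoods: each group has its own mean and scale, the normality
#' parameter nu is shared, and the priors are the broad data-scaled
#' defaults of the reference implementation (normal prior on each mean
#' centered at the pooled mean with SD 1000x the pooled SD; uniform prior
#' on each scale between pooled SD/1000 and pooled SD x 1000; shifted
#' exponential with mean 29 on nu - 1). The posterior of the standardized
#' effect size d = (mu1 - mu2) / sqrt((sigma1^2 + sigma2^2) / 2) is
#' summarized by its mean, a highest-density interval, and the posterior
#' probability of lying outside the region of practical equivalence; the
#' comparison is declared significant when that probability reaches the
#' threshold.
#'
#' @param x,y numeric samples (each n >= 2, nonzero variance).
#' @param rope ROPE bounds on the effect-size scale, default c(-0.1, 0.1).
#' @param threshold decision threshold on P(outside ROPE), default 0.95.
#' @param hdiMass HDI mass, default 0.90.
#' @param draws post-warmup draws per chain, default 2500.
#' @param warmup adaptation + burn-in iterations, default 1000.
#' @param chains MCMC chains, default 4.
#' @param seed integer seed (one sub-seed per chain).
#' @return a [BestFit-class].
#' @examples
#' \donttest{
#' fit <- bestCompare(rnorm(30), rnorm(30, 1), draws = 500, chains = 1,
#'                    seed = 1)
#' effectSize(fit)
#' }
#' @export
bestCompare <- function(x, y, rope = c(-0.1, 0.1), threshold = 0.95,
                        hdiMass = 0.90, draws = 2500, warmup = 1000,
                        chains = 4, seed = 1L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 non-missing values")
  if (sd(x) == 0 && sd(y) == 0)
    stop("degenerate samples: no variance in either group")
  pooled <- c(x, y)
  pooledSD <- sd(pooled)
  if (pooledSD == 0) stop("degenerate samples: pooled SD is zero")
  dat <- list(x = x, y = y, Nx = length(x), Ny = length(y),
              muM = mean(pooled),
              muP = 1 / (1000 * pooledSD)^2,
              sigmaLo = pooledSD / 1000,
              sigmaHi = pooledSD * 1000,
              nuRate = 1 / 29)
  inits <- lapply(seq_len(chains), function(ch) {
    list(mu1 = mean(x), mu2 = mean(y),
         sigma1 = max(sd(x), dat$sigmaLo * 2),
         sigma2 = max(sd(y), dat$sigmaLo * 2),
         nuMinusOne = 29,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = mixSeed(seed, 101L, ch))
  })
  jm <- rjags::jags.model(textConnection(bestModelString), data = dat,
                          inits = inits, n.chains = chains,
                          n.adapt = max(100L, warmup %/% 2L), quiet = TRUE)
  update(jm, n.iter = max(100L, warmup %/% 2L), progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("mu1", "mu2", "sigma1", "sigma2", "nu"),
                              n.iter = draws, progress.bar = "none")
  mat <- as.data.frame(as.matrix(samp))
  d <- (mat$mu1 - mat$mu2) / sqrt((mat$sigma1^2 + mat$sigma2^2) / 2)
  dd <- data.frame(mu1 = mat$mu1, mu2 = mat$mu2, sigma1 = mat$sigma1,
                   sigma2 = mat$sigma2, nu = mat$nu, d = d)
  pOut <- mean(d < rope[1] | d > rope[2])
  hh <- hdi(d, hdiMass)
  ess <- tryCatch(as.numeric(coda::effectiveSize(coda::as.mcmc(d))),
                  error = function(e) NA_real_)
  rhat <- NA_real_
  if (chains > 1L) {
    dChains <- coda::as.mcmc.list(lapply(samp, function(ch) {
      m <- as.matrix(ch)
      coda::as.mcmc((m[, "mu1"] - m[, "mu2"]) /
                      sqrt((m[, "sigma1"]^2 + m[, "sigma2"]^2) / 2))
    }))
    rhat <- tryCatch(coda::gelman.diag(dChains, autoburnin = FALSE)$psrf[1L],
                     error = function(e) NA_real_)
  }
  converged <- is.na(rhat) || rhat < 1.01
  if (!converged)
    warning(sprintf("possible non-convergence: split-Rhat on d = %.3f", rhat))
  new("BestFit", draws = dd, rope = rope, hdiMass = hdiMass,
      effectSize = mean(d), hdi = hh, pOutsideRope = pOut,
      significant = pOut >= threshold, threshold = threshold,
      diagnostics = list(ess = ess, rhat = rhat, converged = converged,
                         chains = chains, drawsPerChain = draws))
}

#' Bayesian comparison grid: every disease group against the controls
#'
#' Runs one robust two-group comparison per (disease group x class x
#' parameter) cell plus the C/D ratio cells, with the disease group as the
#' first sample (so a negative effect size means the parameter is reduced
#' relative to controls). Missing values are dropped pairwise and the
#' per-cell sample sizes are reported.
#'
#' @param stats tidy per-subject statistics (subject, group, class,
#'   occurrence, coverage, meanDuration), e.g. from [cohortStats()].
#' @param ratios tidy per-subject ratio table (subject, group, parameter,
#'   ratio), or NULL to skip ratio cells.
#' @param control name of the control group.
#' @param classes classes to compare, default c("C", "D").
#' @param parameters parameters to compare.
#' @param ... passed to [bestCompare()] (draws, chains, rope, seed, ...).
#' @param seed integer seed; each cell gets a derived sub-seed.
#' @return data.frame with one row per comparison: group, measure,
#'   parameter, n1, n2, effectSize, hdiLow, hdiHigh, pOutsideRope,
#'   significant, rhat; the fitted [BestFit-class] objects in attribute
#'   \code{fits}.
#' @export
compareAll <- function(stats, ratios = NULL, control = "CTRL",
                       classes = c("C", "D"),
                       parameters = c("occurrence", "coverage", "meanDuration"),
                       seed = 1L, ...) {
  groups <- unique(stats$group)
  if (!control %in% groups) stop("control group '", control, "' not found")
  disease <- setdiff(groups, control)
  if (!length(disease)) stop("need at least one non-control group")
  rows <- list()
  fits <- list()
  cell <- 0L
  addCell <- function(g, measure, p, xv, yv) {
    cell <<- cell + 1L
    xv <- xv[!is.na(xv)]
    yv <- yv[!is.na(yv)]
    if (length(xv) < 2L || length(yv) < 2L)
      stop("all-missing or degenerate cell: ", g, " / ", measure, " / ", p)
    fit <- bestCompare(xv, yv, seed = mixSeed(seed, 301L, cell), ...)
    key <- paste(g, measure, p, sep = ".")
    fits[[key]] <<- fit
    rows[[key]] <<- data.frame(
      group = g, measure = measure, parameter = p,
      n1 = length(xv), n2 = length(yv),
      effectSize = fit@effectSize, hdiLow = fit@hdi[1], hdiHigh = fit@hdi[2],
      pOutsideRope = fit@pOutsideRope, significant = fit@significant,
      rhat = if (is.null(fit@diagnostics$rhat)) NA_real_
             else fit@diagnostics$rhat,
      stringsAsFactors = FALSE)
  }
  for (g in disease) {
    for (cl in classes) {
      for (p in parameters) {
        addCell(g, cl, p,
                stats[stats$group == g & stats$class == cl, p],
                stats[stats$group == control & stats$class == cl, p])
      }
    }
    if (!is.null(ratios)) {
      for (p in parameters) {
        addCell(g, "C/D", p,
                ratios[ratios$group == g & ratios$parameter == p, "ratio"],
                ratios[ratios$group == control & ratios$parameter == p,
                       "ratio"])
      }
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "fits") <- fits
  out
}

#' One-way ANOVA adjusted for age and sex, with applicability checks
#'
#' Fits \code{value ~ group + age + sex} and reports the type-II F test
#' for the group factor, together with the applicability checks: Levene's
#' test for homoscedasticity across groups (median-centered) and a
#' Shapiro-Wilk normality test per group.
#'
#' @param values numeric response.
#' @param group factor (>= 2 levels, each n >= 2).
#' @param age,sex covariates (numeric / factor).
#' @return object of class \code{msAnova}: list with \code{F}, \code{df},
#'   \code{p} for the group factor, \code{levene} (statistic, p),
#'   \code{normality} (per-group data.frame), and the fitted \code{model}.
#' @export
anovaAdjusted <- function(values, group, age, sex) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (any(table(group) < 2L)) stop("every group needs n >= 2")
  keep <- complete.cases(values, group, age, sex)
  dat <- data.frame(value = values[keep], group = group[keep],
                    age = age[keep], sex = sex[keep])
  rhs <- "group + age"
  if (length(unique(dat$sex)) > 1L) rhs <- paste(rhs, "+ sex")
  if (length(unique(dat$age)) <= 1L) rhs <- sub("group \\+ age", "group", rhs)
  fit <- lm(stats::as.formula(paste("value ~", rhs)), data = dat)
  if (any(is.na(stats::coef(fit))))
    warning("rank-deficient model: a covariate is confounded or constant")
  a2 <- car::Anova(fit, type = 2)
  gi <- match("group", rownames(a2))
  lev <- car::leveneTest(value ~ group, data = dat, center = median)
  normality <- do.call(rbind, lapply(levels(dat$group), function(g) {
    v <- dat$value[dat$group == g]
    if (length(v) >= 3L && sd(v) > 0) {
      sw <- shapiro.test(v)
      data.frame(group = g, W = unname(sw$statistic), p = sw$p.value,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group = g, W = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }))
  out <- list(F = a2$`F value`[gi],
              df = c(a2$Df[gi], stats::df.residual(fit)),
              p = a2$`Pr(>F)`[gi],
              levene = list(F = lev$`F value`[1L], p = lev$`Pr(>F)`[1L]),
              normality = normality,
              model = fit)
  class(out) <- "msAnova"
  out
}

#' @export
print.msAnova <- function(x, ...) {
  cat(sprintf("Group effect (type II): F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat(sprintf("Levene (median-centered): F = %.3f, p = %.4g\n",
              x$levene$F, x$levene$p))
  cat("Shapiro-Wilk per group:\n")
  print(x$normality, row.names = FALSE)
  invisible(x)
}
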
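#' Pipeline configuration
#'
#' Collects the analysis constants with their standard defaults: 0.5-40 Hz
#' band, "eyes_closed" spans, K = 4 maps (or a silhouette search range),
#' 82 ms smoothing window, ROPE (-0.1, 0.1) with a 0.95 decision threshold
#' and a 90\% HDI.
#'
#' @param band numeric length-2, band-pass edges in Hz.
#' @param segmentLabel annotation label of the spans to analyze.
#' @param K number of microstate maps; set \code{NULL} to choose by
#'   silhouette over \code{kRange}.
#' @param kRange candidate K values when \code{K} is NULL.
#' @param windowMs temporal smoothing full window (ms).
#' @param rope ROPE bounds on the effect-size scale.
#' @param threshold decision threshold on P(outside ROPE).
#' @param hdiMass HDI probability mass.
#' @param control control group name.
#' @param draws,warmup,chains MCMC settings per comparison.
#' @param seed master integer seed.
#' @return a list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(band = c(0.5, 40), segmentLabel = "eyes_closed",
                           K = 4, kRange = 2:7, windowMs = 82,
                           rope = c(-0.1, 0.1), threshold = 0.95,
                           hdiMass = 0.90, control = "CTRL", draws = 2500,
                           warmup = 1000, chains = 4, seed = 1L) {
  cfg <- list(band = band, segmentLabel = segmentLabel, K = K,
              kRange = kRange, windowMs = windowMs, rope = rope,
              threshold = threshold, hdiMass = hdiMass, control = control,
              draws = draws, warmup = warmup, chains = chains,
              seed = as.integer(seed))
  stopifnot(length(band) == 2L, band[1] > 0, band[1] < band[2],
            windowMs > 0, rope[1] < rope[2],
            threshold > 0, threshold <= 1, hdiMass > 0, hdiMass < 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full microstate pipeline on a BIDS-like cohort directory
#'
#' Executes the whole analysis: read every subject's EDF, preprocess
#' (band-pass, eyes-closed segment selection, average reference, at most
#' one interpolated bad channel, alpha-dominance QC), build the microstate
#' maps by two-level clustering in the control group only, label them A-D
#' against the canonical templates, backfit the control maps to every
#' subject (controls included), smooth, compute per-subject statistics and
#' C/D ratios, and run the Bayesian comparison grid plus the
#' covariate-adjusted ANOVA per class and parameter. All tables, a QC
#' manifest and the resolved configuration are written to \code{outDir}.
#'
#' @param cohortDir BIDS-like cohort directory (see [writeCohortBIDS()]).
#' @param outDir output directory for result tables.
#' @param config a \code{PipelineConfig} from [pipelineConfig()].
#' @return invisibly, a list: \code{manifest} (per-subject QC outcome),
#'   \code{maps} (control [MicrostateMaps-class]), \code{stats},
#'   \code{ratios}, \code{comparisons}, \code{anova}, \code{config}.
#' @export
runPipeline <- function(cohortDir, outDir, config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  ptPath <- file.path(cohortDir, "participants.tsv")
  if (!file.exists(ptPath)) stop("no participants.tsv in ", cohortDir)
  participants <- utils::read.delim(ptPath, stringsAsFactors = FALSE)
  if (!config$control %in% participants$group)
    stop("cohort has no control group '", config$control, "'")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  recs <- list()
  manifest <- list()
  for (i in seq_len(nrow(participants))) {
    id <- participants$participant_id[i]
    edf <- file.path(cohortDir, id, "eeg",
                     sprintf("%s_task-rest_eeg.edf", id))
    outcome <- tryCatch({
      rec <- readEDF(edf)
      bads <- readChannelStatus(cohortDir, id)
      if (length(bads)) badChannels(rec) <- bads
      pp <- preprocessRecording(rec, config$band[1], config$band[2],
                                config$segmentLabel)
      if (!pp$alphaDominant) {
        list(included = FALSE, reason = "not alpha-dominant")
      } else {
        recs[[id]] <- pp$recording
        list(included = TRUE, reason = "")
      }
    },
    excludeRecording = function(e) list(included = FALSE,
                                        reason = conditionMessage(e)),
    noUsableSegment = function(e) list(included = FALSE,
                                       reason = conditionMessage(e)))
    manifest[[id]] <- data.frame(subject = id,
                                 group = participants$group[i],
                                 included = outcome$included,
                                 reason = outcome$reason,
                                 stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, c(manifest, make.row.names = FALSE))
  if (!any(manifest$included)) stop("empty cohort after quality control")
  groups <- stats::setNames(participants$group, participants$participant_id)
  ctrlIds <- manifest$subject[manifest$included &
                                manifest$group == config$control]
  if (!length(ctrlIds)) stop("no control subjects left after quality control")

  K <- config$K
  silhouette <- NULL
  if (is.null(K)) {
    pool <- do.call(rbind, lapply(ctrlIds, function(id) {
      peakTopographies(recs[[id]])$maps
    }))
    silhouette <- silhouetteK(pool, config$kRange,
                              seed = mixSeed(config$seed, 7L))
    K <- silhouette$bestK
  }
  ctrlMaps <- twoLevelCluster(recs[ctrlIds], K = K,
                              seed = mixSeed(config$seed, 11L),
                              groupName = config$control)
  if (K == 4L) {
    ctrlMaps <- labelMaps(ctrlMaps, canonicalTemplates())
    ctrlMaps@provenance <- paste0("group:", config$control)
  }

  cs <- cohortStats(recs, ctrlMaps, groups, windowMs = config$windowMs)
  comparisons <- compareAll(cs$stats, cs$ratios, control = config$control,
                            rope = config$rope, threshold = config$threshold,
                            hdiMass = config$hdiMass, draws = config$draws,
                            warmup = config$warmup, chains = config$chains,
                            seed = mixSeed(config$seed, 19L))
  anova <- anovaTable(cs$stats, participants, config$control)

  writeCsv <- function(d, f) write.csv(d, file.path(outDir, f),
                                       row.names = FALSE)
  writeCsv(cs$stats, "microstate_stats.csv")
  writeCsv(cs$ratios, "cd_ratios.csv")
  writeCsv(comparisons[, setdiff(names(comparisons), "fits")],
           "best_comparisons.csv")
  writeCsv(anova, "anova.csv")
  writeCsv(manifest, "manifest.csv")
  mapTab <- as.data.frame(mapMatrix(ctrlMaps))
  mapTab <- cbind(class = classLabels(ctrlMaps), mapTab)
  writeCsv(mapTab, "control_maps.csv")
  resolved <- config
  resolved$K <- K
  yaml::write_yaml(unclass(resolved), file.path(outDir, "config.yaml"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(manifest = manifest, maps = ctrlMaps, stats = cs$stats,
                 ratios = cs$ratios, comparisons = comparisons,
                 anova = anova, silhouette = silhouette, config = resolved))
}

# optional BIDS channels.tsv: channels flagged with status "bad"
readChannelStatus <- function(cohortDir, id) {
  p <- file.path(cohortDir, id, "eeg",
                 sprintf("%s_task-rest_channels.tsv", id))
  if (!file.exists(p)) return(character())
  tab <- utils::read.delim(p, stringsAsFactors = FALSE)
  if (!all(c("name", "status") %in% names(tab))) return(character())
  normalizeChannelNames(tab$name[tolower(tab$status) == "bad"])
}

# deterministic canonical class templates used only to attach A-D letters
# to fitted group maps
canonicalTemplates <- function() {
  makeTemplateMaps(makeLayout(), seed = 0L, perturbation = 0)
}

# per-class, per-parameter covariate-adjusted ANOVA across disease groups
# (controls excluded, mirroring a between-disease comparison)
anovaTable <- function(stats, participants, control) {
  dis <- stats[stats$group != control, ]
  demo <- participants[match(dis$subject, participants$participant_id), ]
  out <- list()
  if (length(unique(dis$group)) >= 2L) {
    for (cl in unique(dis$class)) {
      for (p in c("occurrence", "coverage", "meanDuration")) {
        sel <- dis$class == cl
        res <- tryCatch(
          anovaAdjusted(dis[sel, p], dis$group[sel], demo$age[sel],
                        demo$sex[sel]),
          error = function(e) NULL)
        if (is.null(res)) next
        out[[paste(cl, p)]] <- data.frame(
          class = cl, parameter = p, F = res$F, df1 = res$df[1],
          df2 = res$df[2], p = res$p, leveneF = res$levene$F,
          leveneP = res$levene$p, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(class = character(), parameter = character(),
                  F = numeric(), df1 = numeric(), df2 = numeric(),
                  p = numeric(), leveneF = numeric(), leveneP = numeric())
}

#' Simulate a cohort and write it as a pipeline-ready directory
#'
#' Convenience wrapper: [simulateCohort()] then [writeCohortBIDS()].
#'
#' @param spec a [CohortSpec-class].
#' @param dir output directory.
#' @return the cohort list from [simulateCohort()], invisibly;
#'   ground-truth tables are also available from the written sidecars.
#' @export
simulateCohortDir <- function(spec, dir) {
  cohort <- simulateCohort(spec)
  writeCohortBIDS(cohort, dir)
  invisible(cohort)
}
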
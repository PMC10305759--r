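# Minimal EDF/EDF+ support: 16-bit signals, 1 s data records, one
# EDF Annotations channel carrying the record timestamps and the event
# annotations. Covers what routine resting-state EEG pipelines need;
# it is not a general EDF library.

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = -width)
}

edfNum <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  edfPad(s, width)
}

#' Write a recording as EDF+
#'
#' Writes 16-bit EDF+ with 1 s data records and an annotation channel
#' holding the recording's annotations. Only whole seconds are written
#' (a trailing partial second is dropped with a warning). Physical units
#' are microvolts; the per-channel physical range is fitted to the data,
#' so quantization error is at most range/65536.
#'
#' @param rec an [EEGRecording-class] with an integer sampling rate.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  rate <- rec@rate
  if (abs(rate - round(rate)) > 1e-9)
    stop("writeEDF needs an integer sampling rate")
  rate <- as.integer(round(rate))
  nRec <- ncol(rec@data) %/% rate
  if (nRec < 1L) stop("recording shorter than one data record (1 s)")
  if (nRec * rate < ncol(rec@data))
    warning("dropping a trailing partial second (",
            ncol(rec@data) - nRec * rate, " samples)")
  data <- rec@data[, seq_len(nRec * rate), drop = FALSE]
  nSig <- nrow(data)
  annSamples <- 60L   # 120 bytes per record for the annotation channel
  ns <- nSig + 1L

  physMax <- pmax(apply(abs(data), 1L, max), 1)
  physMax <- signif(physMax * 1.001, 6)
  digMax <- 32767
  scale <- physMax / digMax
  digital <- round(sweep(data, 1L, scale, `/`))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(edfPad("0", 8L), con, eos = NULL)
  writeChar(edfPad("X X X X", 80L), con, eos = NULL)
  writeChar(edfPad("Startdate X X X X", 80L), con, eos = NULL)
  writeChar(edfPad("01.01.00", 8L), con, eos = NULL)
  writeChar(edfPad("00.00.00", 8L), con, eos = NULL)
  writeChar(edfPad((ns + 1L) * 256L, 8L), con, eos = NULL)
  writeChar(edfPad("EDF+C", 44L), con, eos = NULL)
  writeChar(edfPad(nRec, 8L), con, eos = NULL)
  writeChar(edfPad(1, 8L), con, eos = NULL)
  writeChar(edfPad(ns, 4L), con, eos = NULL)

  labels <- c(paste("EEG", rec@layout@channels), "EDF Annotations")
  field <- function(values, width) {
    for (v in values) writeChar(edfPad(v, width), con, eos = NULL)
  }
  field(labels, 16L)
  field(rep("", ns), 80L)
  field(c(rep("uV", nSig), ""), 8L)
  field(c(vapply(-physMax, edfNum, character(1), width = 8L), "-1"), 8L)
  field(c(vapply(physMax, edfNum, character(1), width = 8L), "1"), 8L)
  field(c(rep(-digMax, nSig), -32768), 8L)
  field(rep(digMax, ns), 8L)
  field(rep("", ns), 80L)
  field(c(rep(rate, nSig), annSamples), 8L)
  field(rep("", ns), 32L)

  events <- rec@annotations
  if (nrow(events)) {               # clip annotations to the written length
    events <- events[events$onset < nRec, , drop = FALSE]
    events$duration <- pmin(events$duration, nRec - events$onset)
  }
  for (r in seq_len(nRec) - 1L) {
    block <- digital[, (r * rate + 1L):((r + 1L) * rate), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
    # TALs: a record-timestamp TAL, then (first record only) the events;
    # each TAL is terminated by a 0x00 byte
    tal <- c(charToRaw(sprintf("+%d\x14\x14", r)), as.raw(0L))
    if (r == 0L && nrow(events)) {
      for (i in seq_len(nrow(events))) {
        tal <- c(tal,
                 charToRaw(sprintf("+%g\x15%g\x14%s\x14", events$onset[i],
                                   events$duration[i], events$label[i])),
                 as.raw(0L))
      }
    }
    nBytes <- 2L * annSamples
    if (length(tal) > nBytes) stop("annotation block overflow")
    writeBin(c(tal, raw(nBytes - length(tal))), con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Reads 16-bit EDF signals and EDF+ annotations. EEG channel labels are
#' normalized (an "EEG " prefix is stripped, modern T7/T8/P7/P8 names are
#' mapped to T3/T4/T5/T6) and reordered to the canonical 19-channel 10-20
#' layout, which must be present in full.
#'
#' @param path an EDF/EDF+ file.
#' @return an [EEGRecording-class] with reference "native".
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8L)                       # version
  rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L)                       # header bytes
  rd(44L)                      # reserved / EDF+C
  nRec <- as.integer(rd(8L))
  recDur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1))
  for (i in seq_len(ns)) rd(80L)               # transducer
  for (i in seq_len(ns)) rd(8L)                # dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  for (i in seq_len(ns)) rd(80L)               # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8L)), integer(1))
  for (i in seq_len(ns)) rd(32L)

  isAnn <- labels == "EDF Annotations"
  sig <- which(!isAnn)
  out <- lapply(sig, function(i) matrix(0L, spr[i], nRec))
  annRaw <- list()
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      if (isAnn[i]) {
        annRaw[[length(annRaw) + 1L]] <- readBin(con, "raw",
                                                 n = 2L * spr[i])
      } else {
        out[[match(i, sig)]][, r] <- readBin(con, "integer", n = spr[i],
                                             size = 2L, endian = "little",
                                             signed = TRUE)
      }
    }
  }
  data <- do.call(rbind, lapply(seq_along(sig), function(k) {
    i <- sig[k]
    g <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    as.numeric(out[[k]]) * g + physMin[i] - digMin[i] * g
  }))

  chn <- normalizeChannelNames(sub("^EEG ", "", labels[sig]))
  lay <- makeLayout()
  ord <- match(lay@channels, chn)
  if (anyNA(ord))
    stop("EDF does not contain the full 19-channel 10-20 montage (missing: ",
         paste(setdiff(lay@channels, chn), collapse = ", "), ")")
  data <- data[ord, , drop = FALSE]
  rownames(data) <- lay@channels
  rate <- spr[sig[1L]] / recDur
  ann <- parseTALs(do.call(c, annRaw))
  new("EEGRecording", data = data, rate = rate, layout = lay,
      annotations = ann, bads = character(), reference = "native",
      segments = ncol(data), history = "read_edf")
}

# parse EDF+ time-stamped annotation lists (raw bytes, TALs separated by
# 0x00) into onset/duration/label rows
parseTALs <- function(bytes) {
  out <- data.frame(onset = numeric(), duration = numeric(),
                    label = character(), stringsAsFactors = FALSE)
  if (is.null(bytes) || !length(bytes)) return(out)
  zero <- bytes == as.raw(0L)
  grp <- cumsum(c(TRUE, zero[-length(zero)]))
  tals <- vapply(split(bytes[!zero], grp[!zero]), rawToChar, character(1))
  for (tal in tals) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) next               # bare timestamp
    labels <- parts[-1L]
    labels <- labels[nzchar(labels)]
    if (!length(labels)) next
    od <- strsplit(parts[1L], "\x15", fixed = TRUE)[[1L]]
    onset <- as.numeric(od[1L])
    duration <- if (length(od) > 1L) as.numeric(od[2L]) else 0
    for (lb in labels) {
      out <- rbind(out, data.frame(onset = onset, duration = duration,
                                   label = lb, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Write a simulated cohort as a BIDS-like EDF+ tree
#'
#' Lays out one EDF+ file per subject
#' (\code{sub-XXX/eeg/sub-XXX_task-rest_eeg.edf}), a per-subject
#' ground-truth JSON sidecar (true per-class statistics and generating
#' seed) and a cohort-level \code{participants.tsv} (subject, group, age,
#' sex) — the directory format [runPipeline()] consumes.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohortBIDS <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- cohort$groundTruth
  for (id in names(cohort$recordings)) {
    sd <- file.path(dir, id, "eeg")
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    writeEDF(cohort$recordings[[id]],
             file.path(sd, sprintf("%s_task-rest_eeg.edf", id)))
    truth <- gt$stats[gt$stats$subject == id, ]
    jsonlite::write_json(
      list(subject = id, group = truth$group[1L],
           classes = truth$class,
           occurrence = truth$occurrence, coverage = truth$coverage,
           meanDuration = truth$meanDuration),
      file.path(sd, sprintf("%s_task-rest_truth.json", id)),
      auto_unbox = TRUE, digits = NA)
  }
  pt <- gt$participants
  names(pt)[names(pt) == "subject"] <- "participant_id"
  utils::write.table(pt, file.path(dir, "participants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
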
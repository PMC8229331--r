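# Text spike tables / stimulus logs and the native raw-trace container.
# Files store times in seconds with fixed 6-decimal formatting (tab delimiter,
# '.' decimal) so repeated writes are byte-identical; analysis-facing
# parameters are in ms, converted centrally (msToS/sToMs).

SPIKE_MAGIC <- "# modularMEA spike table v1"
STIM_MAGIC <- "# modularMEA stimulus log v1"
RAW_FORMAT <- "modularMEA-raw-v1"

fmtTime <- function(x) sprintf("%.6f", x)
fmtAmp <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))

parseError <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

writeMetaBlock <- function(meta, layout, con) {
  tb <- layoutTable(layout)
  writeLines(c(
    sprintf("# sampling_rate_hz\t%s", format(meta@samplingRate)),
    sprintf("# duration_s\t%s", fmtTime(meta@duration)),
    sprintf("# chip_type\t%s", meta@chipType),
    sprintf("# div\t%s", format(meta@div)),
    sprintf("# label\t%s", meta@label),
    sprintf("# n_electrodes\t%d", layout@nTotal),
    sprintf("# layout\t%d\t%s\t%s\t%s\t%s\t%s", tb$electrode, tb$region,
            format(tb$channel_index), format(tb$channel_pos),
            format(tb$row), format(tb$col))
  ), con)
}

parseMetaBlock <- function(lines, path) {
  kv <- strsplit(sub("^# ", "", lines), "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  getOne <- function(key) {
    i <- which(keys == key)
    if (!length(i)) parseError(path, 1L, sprintf("missing metadata field '%s'", key))
    kv[[i[1]]][2L]
  }
  layLines <- kv[keys == "layout"]
  if (!length(layLines)) parseError(path, 1L, "missing layout block")
  asInt <- function(x) suppressWarnings(as.integer(x))
  tb <- data.frame(
    electrode = vapply(layLines, function(f) asInt(f[2]), integer(1)),
    region = vapply(layLines, `[`, character(1), 3L),
    channel_index = vapply(layLines, function(f) asInt(f[4]), integer(1)),
    channel_pos = vapply(layLines, function(f) asInt(f[5]), integer(1)),
    row = vapply(layLines, function(f) asInt(f[6]), integer(1)),
    col = vapply(layLines, function(f) asInt(f[7]), integer(1)))
  layout <- new("ElectrodeLayout", table = tb, nTotal = nrow(tb))
  lbl <- getOne("label")
  meta <- recordingMeta(samplingRate = as.numeric(getOne("sampling_rate_hz")),
                        duration = as.numeric(getOne("duration_s")),
                        chipType = getOne("chip_type"),
                        div = suppressWarnings(as.numeric(getOne("div"))),
                        label = if (is.na(lbl)) "" else lbl)
  list(meta = meta, layout = layout)
}

#' Write a spike table to a tab-delimited text file
#'
#' The file carries a commented metadata block (sampling rate, duration, chip
#' type, layout) followed by a header row `electrode  time_s  amplitude_uV`.
#' Column order and number formatting are fixed (times to 6 decimals), so the
#' same table always produces byte-identical files. When no event has an
#' amplitude the column is omitted.
#'
#' @param table a [SpikeTable-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [readSpikeTable()]
#' @export
writeSpikeTable <- function(table, path) {
  stopifnot(is(table, "SpikeTable"))
  validObject(table)
  ev <- table@events
  hasAmp <- any(!is.na(ev$amplitude_uV))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SPIKE_MAGIC, con)
  writeMetaBlock(table@meta, table@layout, con)
  if (hasAmp) {
    writeLines("electrode\ttime_s\tamplitude_uV", con)
    if (nrow(ev))
      writeLines(sprintf("%d\t%s\t%s", ev$electrode, fmtTime(ev$time_s),
                         fmtAmp(ev$amplitude_uV)), con)
  } else {
    writeLines("electrode\ttime_s", con)
    if (nrow(ev))
      writeLines(sprintf("%d\t%s", ev$electrode, fmtTime(ev$time_s)), con)
  }
  invisible(path)
}

#' Read a spike table from a tab-delimited text file
#'
#' Counterpart of [writeSpikeTable()]. All invariants are checked while
#' parsing — unknown electrode ids, negative or unsorted times, and times
#' beyond the recording duration raise an error naming the offending line —
#' so downstream stages always receive validated data.
#'
#' @param path file written by [writeSpikeTable()].
#' @return a [SpikeTable-class].
#' @export
readSpikeTable <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != SPIKE_MAGIC)
    parseError(path, 1L, "not a modularMEA spike table")
  isMeta <- startsWith(lines, "#")
  headerLine <- which(!isMeta)[1]
  if (is.na(headerLine)) parseError(path, length(lines), "missing column header")
  mb <- parseMetaBlock(lines[seq_len(headerLine - 1L)][-1L], path)
  cols <- strsplit(lines[headerLine], "\t", fixed = TRUE)[[1]]
  if (!all(c("electrode", "time_s") %in% cols))
    parseError(path, headerLine, "missing required columns electrode, time_s")
  hasAmp <- "amplitude_uV" %in% cols
  dataLines <- lines[seq.int(headerLine + 1L, length.out = length(lines) - headerLine)]
  n <- length(dataLines)
  electrode <- integer(n); time_s <- numeric(n); amp <- rep(NA_real_, n)
  known <- mb$layout@table$electrode
  dur <- mb$meta@duration
  if (n) {
    fields <- strsplit(dataLines, "\t", fixed = TRUE)
    for (i in seq_len(n)) {
      f <- fields[[i]]
      lineNo <- headerLine + i
      if (length(f) != length(cols))
        parseError(path, lineNo, "wrong number of fields")
      e <- suppressWarnings(as.integer(f[match("electrode", cols)]))
      t <- suppressWarnings(as.numeric(f[match("time_s", cols)]))
      if (is.na(e) || is.na(t)) parseError(path, lineNo, "unparseable field")
      if (!e %in% known) parseError(path, lineNo, sprintf("unknown electrode id %d", e))
      if (t < 0) parseError(path, lineNo, "negative spike time")
      if (t > dur) parseError(path, lineNo, "time outside recording")
      if (i > 1L && t < time_s[i - 1L]) parseError(path, lineNo, "unsorted spike times")
      electrode[i] <- e; time_s[i] <- t
      if (hasAmp) amp[i] <- suppressWarnings(as.numeric(f[match("amplitude_uV", cols)]))
    }
  }
  spikeTable(mb$meta, mb$layout, electrode, time_s, amp)
}

#' Write / read a stimulus log as tab-delimited text
#'
#' `writeStimulusLog()` stores the stimulus times (6-decimal seconds) and the
#' protocol label, with the stimulated electrodes, ISI range, and pulse shape
#' in a commented metadata block; `readStimulusLog()` parses and validates it.
#'
#' @param log a [StimulusLog-class].
#' @param path file path.
#' @return `writeStimulusLog()`: invisibly `path`; `readStimulusLog()`: a
#'   [StimulusLog-class].
#' @export
writeStimulusLog <- function(log, path) {
  stopifnot(is(log, "StimulusLog"))
  validObject(log)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    STIM_MAGIC,
    sprintf("# stim_electrodes\t%s", paste(log@stimElectrodes, collapse = ",")),
    sprintf("# isi_range_s\t%s\t%s", fmtTime(log@isiRange[1]), fmtTime(log@isiRange[2])),
    sprintf("# pulse_amplitude_mV\t%s", format(log@pulseShape$amplitude_mV)),
    sprintf("# pulse_phase_us\t%s", format(log@pulseShape$phase_us)),
    sprintf("# pulse_polarity\t%s", log@pulseShape$polarity),
    "time_s\tprotocol"), con)
  if (length(log@stimTimes))
    writeLines(sprintf("%s\t%s", fmtTime(log@stimTimes), log@protocol), con)
  invisible(path)
}

#' @rdname writeStimulusLog
#' @export
readStimulusLog <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != STIM_MAGIC)
    parseError(path, 1L, "not a modularMEA stimulus log")
  isMeta <- startsWith(lines, "#")
  headerLine <- which(!isMeta)[1]
  kv <- strsplit(sub("^# ", "", lines[seq_len(headerLine - 1L)][-1L]), "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  getOne <- function(key) {
    i <- which(keys == key)
    if (!length(i)) parseError(path, 1L, sprintf("missing metadata field '%s'", key))
    kv[[i[1]]]
  }
  se <- getOne("stim_electrodes")[2L]
  stimElectrodes <- if (is.na(se) || !nzchar(se)) integer(0) else
    as.integer(strsplit(se, ",", fixed = TRUE)[[1]])
  isiRange <- as.numeric(getOne("isi_range_s")[2:3])
  pulse <- list(amplitude_mV = as.numeric(getOne("pulse_amplitude_mV")[2L]),
                phase_us = as.numeric(getOne("pulse_phase_us")[2L]),
                polarity = getOne("pulse_polarity")[2L])
  dataLines <- lines[seq.int(headerLine + 1L, length.out = length(lines) - headerLine)]
  if (!length(dataLines))
    parseError(path, headerLine, "stimulus log has no stimuli")
  fields <- strsplit(dataLines, "\t", fixed = TRUE)
  times <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  prot <- unique(vapply(fields, `[`, character(1), 2L))
  if (length(prot) != 1L)
    parseError(path, headerLine + 1L, "mixed protocol labels in one log")
  stimulusLog(times, stimElectrodes, protocol = prot, isiRange = isiRange,
              pulseShape = pulse)
}

#' Write / read raw voltage traces
#'
#' Raw multi-electrode traces, recording metadata and the electrode layout
#' travel together in the package's native serialized container (one dataset
#' per electrode plus metadata attributes). The round trip is lossless at
#' full double precision.
#'
#' @param raw a [RawSignalSet-class].
#' @param path file path (conventionally `.rds`).
#' @return `writeRaw()`: invisibly `path`; `readRaw()`: a
#'   [RawSignalSet-class].
#' @export
writeRaw <- function(raw, path) {
  stopifnot(is(raw, "RawSignalSet"))
  validObject(raw)
  payload <- list(format = RAW_FORMAT,
                  meta = list(sampling_rate_hz = raw@meta@samplingRate,
                              duration_s = raw@meta@duration,
                              div = raw@meta@div,
                              chip_type = raw@meta@chipType,
                              label = raw@meta@label),
                  layout = layoutTable(raw@layout),
                  samples = raw@samples)
  saveRDS(payload, path, compress = FALSE)
  invisible(path)
}

#' @rdname writeRaw
#' @export
readRaw <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, RAW_FORMAT))
    stop("not a modularMEA raw-signal container: ", path, call. = FALSE)
  m <- payload$meta
  if (is.null(m$sampling_rate_hz) || is.na(m$sampling_rate_hz))
    stop("raw container is missing the sampling rate", call. = FALSE)
  meta <- recordingMeta(samplingRate = m$sampling_rate_hz, duration = m$duration_s,
                        chipType = m$chip_type, div = m$div, label = m$label)
  layout <- new("ElectrodeLayout", table = payload$layout,
                nTotal = nrow(payload$layout))
  new("RawSignalSet", meta = meta, layout = layout, samples = payload$samples)
}
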
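#' Default electrode layout for a modular MEA chip
#'
#' Builds the idealized layout of a 60-electrode array mounted under a
#' two-chamber microfluidic chip: 8 instrumented microchannels carrying 3
#' electrodes each (positions 1..3, Source end to Target end), one reference
#' electrode, and the remaining 35 electrodes split 18 to the Source chamber
#' and 17 to the Target chamber. The chamber split is a fixed documented
#' convention: all analyses group electrodes by region label, never by id
#' arithmetic, so any fixed split is equivalent. Both chip geometries use the
#' same electrode arrangement; `chipType` matters downstream only for the
#' evoked-response window.
#'
#' @param chipType `"fish"` or `"octopus"`.
#' @return an [ElectrodeLayout-class] with 60 electrodes (59 active).
#' @examples
#' lay <- defaultLayout("fish")
#' table(layoutTable(lay)$region)
#' @export
defaultLayout <- function(chipType = c("fish", "octopus")) {
  chipType <- match.arg(chipType)
  region <- c(rep("source_chamber", 18L),
              rep("microchannel", 24L),
              rep("target_chamber", 17L),
              "reference")
  channel_index <- rep(NA_integer_, 60L)
  channel_pos <- rep(NA_integer_, 60L)
  mc <- which(region == "microchannel")
  channel_index[mc] <- rep(0:7, each = 3L)
  channel_pos[mc] <- rep(1:3, times = 8L)
  # 8x8 grid minus the four corners, row-major over the 60 ids
  grid <- expand.grid(col = 1:8, row = 1:8)
  grid <- grid[!(grid$row %in% c(1L, 8L) & grid$col %in% c(1L, 8L)), ]
  tb <- data.frame(electrode = 1:60,
                   region = region,
                   channel_index = channel_index,
                   channel_pos = channel_pos,
                   row = grid$row, col = grid$col)
  new("ElectrodeLayout", table = tb, nTotal = 60L)
}

#' Electrodes belonging to one module
#'
#' Returns the electrode ids grouped into the `"source"` or `"target"` module.
#' By default only chamber electrodes count. With `includeChannels = TRUE`,
#' microchannel electrodes are attributed to the module at their end of the
#' channel: position 1 to Source, position 3 to Target; the middle electrode
#' (position 2) belongs to neither.
#'
#' @param layout an [ElectrodeLayout-class].
#' @param module `"source"` or `"target"`.
#' @param includeChannels also include the channel-end electrodes of the side.
#' @return integer electrode ids.
#' @export
moduleElectrodes <- function(layout, module = c("source", "target"),
                             includeChannels = FALSE) {
  module <- match.arg(module)
  tb <- layoutTable(layout)
  chamber <- if (module == "source") "source_chamber" else "target_chamber"
  ids <- tb$electrode[tb$region == chamber]
  if (includeChannels) {
    pos <- if (module == "source") 1L else 3L
    ids <- c(ids, tb$electrode[tb$region == "microchannel" &
                                 !is.na(tb$channel_pos) & tb$channel_pos == pos])
  }
  sort(ids)
}

#' Construct recording metadata
#'
#' @param samplingRate sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param chipType `"fish"` or `"octopus"`.
#' @param div culture age in days in vitro (optional).
#' @param label free-text label.
#' @return a [RecordingMeta-class].
#' @export
recordingMeta <- function(samplingRate = 20000, duration, chipType = "fish",
                          div = NA_real_, label = "") {
  new("RecordingMeta", samplingRate = as.numeric(samplingRate),
      duration = as.numeric(duration), div = as.numeric(div),
      chipType = chipType, label = label)
}

#' Construct a spike table
#'
#' Events are sorted by time (then electrode) and validated against the
#' layout and recording duration.
#'
#' @param meta a [RecordingMeta-class].
#' @param layout an [ElectrodeLayout-class].
#' @param electrode integer electrode ids, one per spike.
#' @param time_s spike times in seconds.
#' @param amplitude_uV optional spike amplitudes in microvolts.
#' @return a [SpikeTable-class].
#' @export
spikeTable <- function(meta, layout, electrode = integer(0),
                       time_s = numeric(0), amplitude_uV = NULL) {
  if (is.null(amplitude_uV)) amplitude_uV <- rep(NA_real_, length(time_s))
  ev <- data.frame(electrode = as.integer(electrode),
                   time_s = as.numeric(time_s),
                   amplitude_uV = as.numeric(amplitude_uV))
  ev <- ev[order(ev$time_s, ev$electrode), , drop = FALSE]
  rownames(ev) <- NULL
  new("SpikeTable", meta = meta, layout = layout, events = ev)
}

#' Construct a stimulus log
#'
#' @param stimTimes stimulus times in seconds, strictly increasing.
#' @param stimElectrodes stimulated electrode ids.
#' @param protocol `"test1"`, `"test2"`, `"test3"` or `"tetanus"`.
#' @param isiRange declared ISI range (s) for test protocols.
#' @param pulseShape pulse metadata; defaults to the biphasic
#'   +/-800 mV, 260 us/phase, positive-first probe pulse.
#' @return a [StimulusLog-class].
#' @export
stimulusLog <- function(stimTimes, stimElectrodes = integer(0),
                        protocol = "test1", isiRange = c(1, 5),
                        pulseShape = list(amplitude_mV = 800, phase_us = 260,
                                          polarity = "positive_first")) {
  new("StimulusLog", stimTimes = as.numeric(stimTimes),
      stimElectrodes = as.integer(stimElectrodes), protocol = protocol,
      pulseShape = pulseShape, isiRange = as.numeric(isiRange))
}
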
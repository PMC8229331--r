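#' @import methods
NULL

#' Electrode layout of a modular MEA chip
#'
#' Assigns each electrode of the array to a region of the two-chamber
#' microfluidic device: the Source chamber, one of the instrumented
#' microchannels, the Target chamber, or the reference electrode.
#' Microchannel electrodes additionally carry the index of their channel and
#' their position along it (1 = Source end, 3 = Target end).
#'
#' @slot table data.frame with columns `electrode` (integer id), `region`
#'   (one of `"source_chamber"`, `"microchannel"`, `"target_chamber"`,
#'   `"reference"`), `channel_index` (integer, `NA` outside channels),
#'   `channel_pos` (integer 1..3, `NA` outside channels), `row`, `col`
#'   (grid coordinates, may be `NA`).
#' @slot nTotal declared total number of electrodes.
#'
#' @seealso [defaultLayout()]
#' @export
setClass("ElectrodeLayout",
  slots = c(table = "data.frame", nTotal = "integer"))

setValidity("ElectrodeLayout", function(object) {
  tb <- object@table
  need <- c("electrode", "region", "channel_index", "channel_pos", "row", "col")
  if (!all(need %in% names(tb)))
    return(paste("layout table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$electrode)) return("electrode ids must be unique")
  if (!all(tb$region %in% REGIONS))
    return(paste("unknown region; must be one of:", paste(REGIONS, collapse = ", ")))
  mc <- tb$region == "microchannel"
  if (any(is.na(tb$channel_index[mc])))
    return("every microchannel electrode needs a channel_index")
  if (any(is.na(tb$channel_pos[mc])) || any(!tb$channel_pos[mc] %in% 1:3))
    return("every microchannel electrode needs a channel_pos in 1..3")
  if (sum(tb$region == "reference") > 1L) return("at most one reference electrode")
  if (nrow(tb) != object@nTotal)
    return(sprintf("layout has %d electrodes but declares %d", nrow(tb), object@nTotal))
  TRUE
})

#' Recording metadata
#'
#' @slot samplingRate sampling rate in Hz (20000 for the supported system).
#' @slot duration recording duration in seconds.
#' @slot div culture age in days in vitro; `NA` if unknown.
#' @slot chipType `"fish"` or `"octopus"` microchannel geometry; determines
#'   the default post-stimulus analysis window (see [defaultWindow()]).
#' @slot label free-text recording label.
#' @export
setClass("RecordingMeta",
  slots = c(samplingRate = "numeric", duration = "numeric", div = "numeric",
            chipType = "character", label = "character"))

setValidity("RecordingMeta", function(object) {
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  if (length(object@duration) != 1L || object@duration <= 0)
    return("duration must be a single positive number")
  if (!object@chipType %in% c("fish", "octopus"))
    return("chipType must be 'fish' or 'octopus'")
  TRUE
})

#' Table of detected or simulated spikes
#'
#' Multi-unit spike events pooled over electrodes: one row per spike with the
#' electrode id, the spike time in seconds, and (optionally) the extremum
#' amplitude in microvolts. Events are kept sorted by time.
#'
#' @slot meta a [RecordingMeta-class].
#' @slot layout an [ElectrodeLayout-class]; every event's electrode must be in it.
#' @slot events data.frame with columns `electrode`, `time_s`, `amplitude_uV`
#'   (all-`NA` amplitude column when unavailable).
#' @export
setClass("SpikeTable",
  slots = c(meta = "RecordingMeta", layout = "ElectrodeLayout",
            events = "data.frame"))

setValidity("SpikeTable", function(object) {
  ev <- object@events
  need <- c("electrode", "time_s", "amplitude_uV")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (any(ev$time_s < 0) || any(ev$time_s > object@meta@duration))
      return("spike times must lie in [0, duration]")
    if (is.unsorted(ev$time_s)) return("events must be sorted by time")
    if (!all(ev$electrode %in% object@layout@table$electrode))
      return("event electrode id not present in layout")
  }
  TRUE
})

#' Raw multi-electrode voltage traces
#'
#' @slot meta a [RecordingMeta-class].
#' @slot layout an [ElectrodeLayout-class].
#' @slot samples named list (by electrode id) of numeric voltage vectors in
#'   microvolts; all of length `round(duration * samplingRate)`.
#' @export
setClass("RawSignalSet",
  slots = c(meta = "RecordingMeta", layout = "ElectrodeLayout",
            samples = "list"))

setValidity("RawSignalSet", function(object) {
  n <- round(object@meta@duration * object@meta@samplingRate)
  len <- vapply(object@samples, length, integer(1))
  if (length(len) && !all(len == n))
    return(sprintf("all traces must have %d samples (duration x sampling rate)", n))
  if (is.null(names(object@samples)) && length(object@samples))
    return("samples must be named by electrode id")
  if (!all(names(object@samples) %in% as.character(object@layout@table$electrode)))
    return("trace electrode id not present in layout")
  TRUE
})

#' Stimulation log
#'
#' Times and sites of electrical stimulation, with the protocol step label.
#' Test protocols are low-frequency probe trains (inter-stimulus intervals
#' inside `isiRange`); the tetanus protocol is 20 trains of 10 pulses with
#' 50 ms between pulses and 5 s between trains.
#'
#' @slot stimTimes stimulus onset times in seconds, strictly increasing.
#' @slot stimElectrodes electrode ids receiving the pulses.
#' @slot protocol one of `"test1"`, `"test2"`, `"test3"`, `"tetanus"`.
#' @slot pulseShape list describing the biphasic pulse (amplitude_mV,
#'   phase_us, polarity) kept as metadata only.
#' @slot isiRange declared inter-stimulus interval range in seconds for test
#'   protocols.
#' @export
setClass("StimulusLog",
  slots = c(stimTimes = "numeric", stimElectrodes = "integer",
            protocol = "character", pulseShape = "list", isiRange = "numeric"))

setValidity("StimulusLog", function(object) {
  t <- object@stimTimes
  if (length(t) > 1L && any(diff(t) <= 0))
    return("stimulus times must be strictly increasing")
  if (!object@protocol %in% PROTOCOLS)
    return(paste("protocol must be one of:", paste(PROTOCOLS, collapse = ", ")))
  if (object@protocol == "tetanus") {
    if (length(t) != 200L)
      return("tetanus protocol must have exactly 200 pulses (20 trains of 10)")
    within <- diff(t)[rep(c(rep(TRUE, 9L), FALSE), 20L)[-200L]]
    if (any(abs(within - 0.05) > 1e-9))
      return("tetanus within-train intervals must be 50 ms")
  } else if (length(t) > 1L) {
    isi <- diff(t)
    if (any(isi < object@isiRange[1] - 1e-9) || any(isi > object@isiRange[2] + 1e-9))
      return(sprintf("test-protocol inter-stimulus intervals must be within [%g, %g] s",
                     object@isiRange[1], object@isiRange[2]))
  }
  TRUE
})

#' Network bursts of one module
#'
#' @slot module `"source"` or `"target"`.
#' @slot table data.frame with one row per burst: `onset`, `offset`,
#'   `peak_time` (s), `duration_ms`, `n_spikes`, `n_active` (distinct
#'   electrodes), `edge` (TRUE when the burst touches a recording edge; such
#'   bursts are excluded from duration statistics).
#' @export
setClass("BurstSet", slots = c(module = "character", table = "data.frame"))

setValidity("BurstSet", function(object) {
  if (!object@module %in% MODULES) return("module must be 'source' or 'target'")
  tb <- object@table
  need <- c("onset", "offset", "peak_time", "duration_ms", "n_spikes",
            "n_active", "edge")
  if (!all(need %in% names(tb)))
    return(paste("burst table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tb)) {
    if (any(tb$offset <= tb$onset)) return("burst offset must exceed onset")
    if (any(tb$peak_time < tb$onset | tb$peak_time > tb$offset))
      return("peak_time must lie within [onset, offset]")
    if (is.unsorted(tb$onset)) return("bursts must be sorted by onset")
    if (nrow(tb) > 1L && any(tb$onset[-1L] < tb$offset[-nrow(tb)]))
      return("bursts must be disjoint")
  }
  TRUE
})

#' Post-stimulus time histogram matrix
#'
#' Per-electrode, per-bin mean spike counts per stimulus: raw counts over all
#' stimuli divided by the number of stimuli, on 2 ms latency bins inside the
#' post-stimulus analysis window.
#'
#' @slot counts electrodes x bins matrix of mean spikes per stimulus
#'   (rownames are electrode ids); equals `raw / nStimuli`.
#' @slot raw electrodes x bins integer matrix of total in-window spike counts
#'   over all stimuli.
#' @slot binEdges latency bin edges in ms post-stimulus.
#' @slot nStimuli number of stimuli the counts are normalized by.
#' @slot windowMs `(start, end)` of the analysis window in ms.
#' @export
setClass("PSTHMatrix",
  slots = c(counts = "matrix", raw = "matrix", binEdges = "numeric",
            nStimuli = "integer", windowMs = "numeric"))

setValidity("PSTHMatrix", function(object) {
  if (ncol(object@counts) != length(object@binEdges) - 1L)
    return("counts must have one column per bin")
  if (any(object@counts < 0)) return("PSTH counts must be non-negative")
  if (!is.integer(object@raw) || !identical(dim(object@raw), dim(object@counts)))
    return("raw must be an integer matrix matching counts")
  if (any(abs(object@counts * object@nStimuli - object@raw) > 1e-8))
    return("counts must equal raw / nStimuli")
  if (length(object@windowMs) != 2L || object@windowMs[2] <= object@windowMs[1])
    return("windowMs must be (start, end) with end > start")
  TRUE
})

#' Outcome of a tetanus plasticity experiment
#'
#' Per-electrode spontaneous (PRE = test2 - test1) and tetanus-induced
#' (POST = test3 - test2) changes in mean PSTH, the rank-sum comparison of
#' the two samples, and the resulting class label.
#'
#' @slot preDiffs,postDiffs named numeric vectors (by electrode id).
#' @slot statistic Mann-Whitney U statistic.
#' @slot pValue two-sided p-value.
#' @slot alpha significance level used for the label.
#' @slot label `"potentiation"`, `"depression"`, or `"none"`.
#' @slot avgMagnitude mean |POST difference| over the module's electrodes;
#'   `NA` when the label is `"none"`.
#' @slot excluded electrode ids dropped because they were silent in all tests.
#' @export
setClass("PlasticityResult",
  slots = c(preDiffs = "numeric", postDiffs = "numeric", statistic = "numeric",
            pValue = "numeric", alpha = "numeric", label = "character",
            avgMagnitude = "numeric", excluded = "integer"))

setValidity("PlasticityResult", function(object) {
  if (!object@label %in% c("potentiation", "depression", "none"))
    return("label must be potentiation, depression or none")
  if (!identical(names(object@preDiffs), names(object@postDiffs)))
    return("preDiffs and postDiffs must be paired by electrode id")
  TRUE
})

#' Burst-propagation summary for one recording
#'
#' Forward probability is the number of bursts propagated Source to Target
#' divided by the Source burst count; backward is Target to Source divided by
#' the Target burst count. Undefined ratios (zero denominator) are `NA`.
#'
#' @slot nSourceBursts,nTargetBursts burst counts per module.
#' @slot nForward,nBackward,nZeroDelay classified propagation-event counts.
#' @slot pForward,pBackward propagation probabilities (`NA` when undefined).
#' @slot events data.frame of classified events (indices into the burst
#'   tables, peak times, delay in ms, direction).
#' @export
setClass("PropagationSummary",
  slots = c(nSourceBursts = "integer", nTargetBursts = "integer",
            nForward = "integer", nBackward = "integer", nZeroDelay = "integer",
            pForward = "numeric", pBackward = "numeric", events = "data.frame"))

setValidity("PropagationSummary", function(object) {
  ok <- function(p) is.na(p) || (p >= 0 && p <= 1)
  if (!ok(object@pForward) || !ok(object@pBackward))
    return("propagation probabilities must be in [0, 1] or NA")
  if (object@nForward > min(object@nSourceBursts, object@nTargetBursts))
    return("nForward cannot exceed either module's burst count")
  TRUE
})

#' Simulator configuration
#'
#' Parameters of the two-module network generator. Rates are per electrode
#' unless stated; durations/delays/latencies in ms; times in seconds.
#'
#' @slot seed integer RNG seed; identical seed + config give identical output.
#' @slot duration recording length in s.
#' @slot chipType `"fish"` or `"octopus"` (sets the evoked analysis window).
#' @slot burstRate Source network-burst rate, bursts/min.
#' @slot burstDurationMean,burstDurationSd burst envelope width, ms
#'   (truncated at >= 20 ms).
#' @slot intraBurstPeakRate per-electrode spike rate at the envelope peak,
#'   spikes/s.
#' @slot backgroundRate homogeneous background rate, spikes/s per electrode.
#' @slot pForward probability a Source burst propagates to the Target.
#' @slot pBackward probability an autonomous Target burst back-propagates.
#' @slot targetAutonomousRate autonomous Target burst rate, bursts/min.
#' @slot propagationDelayMean,propagationDelaySd peak-to-peak propagation
#'   delay, ms (truncated > 0).
#' @slot evokedWeight synaptic efficacy scaling Target evoked spike counts.
#' @slot evokedLatencyMean,evokedLatencySd evoked-spike latency, ms.
#' @slot tetanusEffect multiplicative change of `evokedWeight` applied by a
#'   tetanus (>1 potentiation, <1 depression, 1 none).
#' @slot baseCount expected evoked spikes per Target electrode per stimulus
#'   at unit weight.
#' @slot retroFraction Source retrograde response share of `baseCount`.
#' @slot noiseSigma Gaussian noise SD for raw-trace synthesis, uV.
#' @slot spikeAmplitude negative-peak spike amplitude for raw synthesis, uV.
#' @export
setClass("SimConfig",
  slots = c(seed = "integer", duration = "numeric", chipType = "character",
            burstRate = "numeric", burstDurationMean = "numeric",
            burstDurationSd = "numeric", intraBurstPeakRate = "numeric",
            backgroundRate = "numeric", pForward = "numeric",
            pBackward = "numeric", targetAutonomousRate = "numeric",
            propagationDelayMean = "numeric", propagationDelaySd = "numeric",
            evokedWeight = "numeric", evokedLatencyMean = "numeric",
            evokedLatencySd = "numeric", tetanusEffect = "numeric",
            baseCount = "numeric", retroFraction = "numeric",
            noiseSigma = "numeric", spikeAmplitude = "numeric"))

setValidity("SimConfig", function(object) {
  pr <- c(object@pForward, object@pBackward)
  if (any(pr < 0 | pr > 1)) return("probabilities must be in [0, 1]")
  rates <- c(object@burstRate, object@backgroundRate, object@targetAutonomousRate,
             object@intraBurstPeakRate, object@baseCount, object@retroFraction,
             object@evokedWeight, object@tetanusEffect)
  if (any(rates < 0)) return("rates and weights must be >= 0")
  if (object@propagationDelaySd < 0 || object@evokedLatencySd < 0 ||
      object@burstDurationSd < 0)
    return("standard deviations must be >= 0")
  if (object@duration <= 0) return("duration must be positive")
  if (!object@chipType %in% c("fish", "octopus"))
    return("chipType must be 'fish' or 'octopus'")
  TRUE
})

#' Ground truth emitted by the simulator
#'
#' @slot sourceBursts,targetBursts data.frames of true bursts
#'   (`onset`, `offset`, `peak_time` in s).
#' @slot propagationEvents data.frame with `source_idx`, `target_idx`
#'   (row indices into the burst tables), `direction`, `delay_ms`.
#' @slot evokedCounts stimuli x electrodes matrix of intended evoked spike
#'   counts (evoked simulations only; 0 x 0 otherwise).
#' @export
setClass("SimTruth",
  slots = c(sourceBursts = "data.frame", targetBursts = "data.frame",
            propagationEvents = "data.frame", evokedCounts = "matrix"))

setValidity("SimTruth", function(object) {
  pe <- object@propagationEvents
  if (nrow(pe)) {
    if (any(pe$source_idx < 1L | pe$source_idx > nrow(object@sourceBursts)))
      return("propagation event references a missing source burst")
    if (any(pe$target_idx < 1L | pe$target_idx > nrow(object@targetBursts)))
      return("propagation event references a missing target burst")
    if (!all(pe$direction %in% c("forward", "backward")))
      return("direction must be forward or backward")
    if (any(pe$delay_ms <= 0))
      return("propagation delays must be positive in the propagating frame")
  }
  TRUE
})
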
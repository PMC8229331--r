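#' @include AllClasses.R
NULL

#' Accessors for modularMEA classes
#'
#' Small accessor generics: `samplingRate()` and `recordingDuration()` read
#' recording metadata, `chipType()` the chip geometry, `spikeEvents()` the
#' event table of a [SpikeTable-class], `electrodeLayout()` and
#' `layoutTable()` the layout, `burstTable()` the burst data.frame of a
#' [BurstSet-class], `psthCounts()` the normalized PSTH matrix, and
#' `nStimuli()` its stimulus count.
#'
#' @param x an object of the documented classes.
#' @return the slot value (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setGeneric("chipType", function(x) standardGeneric("chipType"))
#' @rdname accessors
#' @export
setGeneric("spikeEvents", function(x) standardGeneric("spikeEvents"))
#' @rdname accessors
#' @export
setGeneric("electrodeLayout", function(x) standardGeneric("electrodeLayout"))
#' @rdname accessors
#' @export
setGeneric("layoutTable", function(x) standardGeneric("layoutTable"))
#' @rdname accessors
#' @export
setGeneric("burstTable", function(x) standardGeneric("burstTable"))
#' @rdname accessors
#' @export
setGeneric("psthCounts", function(x) standardGeneric("psthCounts"))
#' @rdname accessors
#' @export
setGeneric("psthRawCounts", function(x) standardGeneric("psthRawCounts"))
#' @rdname accessors
#' @export
setGeneric("nStimuli", function(x) standardGeneric("nStimuli"))

#' @rdname accessors
setMethod("samplingRate", "RecordingMeta", function(x) x@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "SpikeTable", function(x) x@meta@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "RawSignalSet", function(x) x@meta@samplingRate)
#' @rdname accessors
setMethod("recordingDuration", "RecordingMeta", function(x) x@duration)
#' @rdname accessors
setMethod("recordingDuration", "SpikeTable", function(x) x@meta@duration)
#' @rdname accessors
setMethod("recordingDuration", "RawSignalSet", function(x) x@meta@duration)
#' @rdname accessors
setMethod("chipType", "RecordingMeta", function(x) x@chipType)
#' @rdname accessors
setMethod("chipType", "SpikeTable", function(x) x@meta@chipType)
#' @rdname accessors
setMethod("chipType", "RawSignalSet", function(x) x@meta@chipType)
#' @rdname accessors
setMethod("spikeEvents", "SpikeTable", function(x) x@events)
#' @rdname accessors
setMethod("electrodeLayout", "SpikeTable", function(x) x@layout)
#' @rdname accessors
setMethod("electrodeLayout", "RawSignalSet", function(x) x@layout)
#' @rdname accessors
setMethod("layoutTable", "ElectrodeLayout", function(x) x@table)
#' @rdname accessors
setMethod("burstTable", "BurstSet", function(x) x@table)
#' @rdname accessors
setMethod("psthCounts", "PSTHMatrix", function(x) x@counts)
#' @rdname accessors
setMethod("psthRawCounts", "PSTHMatrix", function(x) x@raw)
#' @rdname accessors
setMethod("nStimuli", "PSTHMatrix", function(x) x@nStimuli)

setMethod("show", "ElectrodeLayout", function(object) {
  cnt <- table(factor(object@table$region, levels = REGIONS))
  cat(sprintf("ElectrodeLayout: %d electrodes (%d source, %d microchannel, %d target, %d reference)\n",
              object@nTotal, cnt["source_chamber"], cnt["microchannel"],
              cnt["target_chamber"], cnt["reference"]))
})

setMethod("show", "SpikeTable", function(object) {
  cat(sprintf("SpikeTable: %d spikes on %d electrodes, %.1f s @ %g Hz (%s chip)\n",
              nrow(object@events), length(unique(object@events$electrode)),
              object@meta@duration, object@meta@samplingRate, object@meta@chipType))
})

setMethod("show", "RawSignalSet", function(object) {
  cat(sprintf("RawSignalSet: %d traces x %d samples, %.1f s @ %g Hz\n",
              length(object@samples),
              if (length(object@samples)) length(object@samples[[1]]) else 0L,
              object@meta@duration, object@meta@samplingRate))
})

setMethod("show", "StimulusLog", function(object) {
  cat(sprintf("StimulusLog: %s, %d stimuli on electrodes {%s}\n",
              object@protocol, length(object@stimTimes),
              paste(object@stimElectrodes, collapse = ", ")))
})

setMethod("show", "BurstSet", function(object) {
  tb <- object@table
  kept <- tb[!tb$edge, , drop = FALSE]
  cat(sprintf("BurstSet (%s): %d bursts", object@module, nrow(tb)))
  if (nrow(kept))
    cat(sprintf(", duration %.0f +/- %.0f ms",
                mean(kept$duration_ms), stats::sd(kept$duration_ms)))
  cat("\n")
})

setMethod("show", "PSTHMatrix", function(object) {
  cat(sprintf("PSTHMatrix: %d electrodes x %d bins (%g-%g ms, 2 ms bins), %d stimuli\n",
              nrow(object@counts), ncol(object@counts),
              object@windowMs[1], object@windowMs[2], object@nStimuli))
})

setMethod("show", "PropagationSummary", function(object) {
  fmt <- function(p) if (is.na(p)) "NA" else sprintf("%.3f", p)
  cat(sprintf(paste0("PropagationSummary: %d source / %d target bursts; ",
                     "%d forward, %d backward; p_forward = %s, p_backward = %s\n"),
              object@nSourceBursts, object@nTargetBursts,
              object@nForward, object@nBackward,
              fmt(object@pForward), fmt(object@pBackward)))
})

setMethod("show", "PlasticityResult", function(object) {
  cat(sprintf("PlasticityResult: %s (U = %g, p = %.4g, alpha = %g)\n",
              object@label, object@statistic, object@pValue, object@alpha))
  if (!is.na(object@avgMagnitude))
    cat(sprintf("  averaged |POST difference| = %.3f spikes/stimulus\n",
                object@avgMagnitude))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig (seed %d): %.0f s, %s chip, %g bursts/min, ",
                     "p_forward %.2f, p_backward %.2f, tetanus effect %g\n"),
              object@seed, object@duration, object@chipType, object@burstRate,
              object@pForward, object@pBackward, object@tetanusEffect))
})
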
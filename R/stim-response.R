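#' Default post-stimulus analysis window
#'
#' The analysis window starts 10 ms after the stimulus (excluding the
#' stimulus artifact) and extends to 200 ms for Fish-type chips or 110 ms
#' for Octopus-type chips, always with 2 ms bins — 95 and 50 bins
#' respectively.
#'
#' @param chipType `"fish"` or `"octopus"`.
#' @return numeric `(start, end)` in ms.
#' @export
defaultWindow <- function(chipType = c("fish", "octopus")) {
  chipType <- match.arg(chipType)
  if (chipType == "fish") c(10, 200) else c(10, 110)
}

#' Post-stimulus time histogram
#'
#' For every recording electrode and every stimulus, spikes with latency
#' (spike time minus stimulus time) in `[window[1], window[2])` ms are
#' histogrammed into `bin`-ms half-open bins; counts are summed over stimuli
#' and divided by the number of stimuli, giving mean spikes per stimulus per
#' bin. Overlapping analysis windows (an inter-stimulus interval shorter than
#' the window end) are an error naming the offending stimulus pair.
#'
#' @param spikes a [SpikeTable-class].
#' @param log a [StimulusLog-class] with at least one stimulus.
#' @param window `(start, end)` ms; defaults to the chip's window.
#' @param bin bin width, ms; must divide the window length.
#' @return a [PSTHMatrix-class] over all active (non-reference) electrodes.
#' @export
computePSTH <- function(spikes, log, window = defaultWindow(chipType(spikes)),
                        bin = 2) {
  stopifnot(is(spikes, "SpikeTable"), is(log, "StimulusLog"))
  stopIfNot(length(log@stimTimes) >= 1L, "stimulus log has no stimuli")
  stopIfNot(window[1] >= 0, "window start must be >= 0")
  nb <- (window[2] - window[1]) / bin
  stopIfNot(abs(nb - round(nb)) < 1e-9, "bin must divide the window length")
  nb <- as.integer(round(nb))
  st <- log@stimTimes
  if (length(st) > 1L) {
    isi <- diff(st)
    bad <- which(isi < msToS(window[2]))
    if (length(bad))
      stop(sprintf("analysis windows overlap: stimuli %d and %d are %.1f ms apart (< %g ms window)",
                   bad[1], bad[1] + 1L, sToMs(isi[bad[1]]), window[2]), call. = FALSE)
  }
  tb <- layoutTable(electrodeLayout(spikes))
  electrodes <- tb$electrode[tb$region != "reference"]
  ev <- spikeEvents(spikes)
  counts <- matrix(0, nrow = length(electrodes), ncol = nb,
                   dimnames = list(as.character(electrodes), NULL))
  if (nrow(ev)) {
    # latency relative to the most recent stimulus at or before each spike
    stimIdx <- findInterval(ev$time_s, st)
    has <- stimIdx >= 1L
    lat <- sToMs(ev$time_s[has] - st[stimIdx[has]])
    e <- ev$electrode[has]
    inWin <- lat >= window[1] & lat < window[2]
    if (any(inWin)) {
      binIdx <- floor((lat[inWin] - window[1]) / bin) + 1L
      rowIdx <- match(e[inWin], electrodes)
      for (k in seq_along(binIdx))
        counts[rowIdx[k], binIdx[k]] <- counts[rowIdx[k], binIdx[k]] + 1
    }
  }
  raw <- counts
  storage.mode(raw) <- "integer"
  new("PSTHMatrix", counts = counts / length(st), raw = raw,
      binEdges = seq(window[1], window[2], by = bin),
      nStimuli = length(st), windowMs = as.numeric(window))
}

#' Mean PSTH: evoked spikes per stimulus
#'
#' The mean PSTH of an electrode is the sum of its PSTH bins — the average
#' number of stimulus-evoked spikes per stimulus in the analysis window. The
#' module mean is the arithmetic mean of the per-electrode values over the
#' requested electrode subset.
#'
#' @param m a [PSTHMatrix-class].
#' @param electrodes electrode ids to average over (non-empty subset of the
#'   matrix rows).
#' @return list with `perElectrode` (named numeric) and `moduleMean`.
#' @export
meanPSTH <- function(m, electrodes = as.integer(rownames(psthCounts(m)))) {
  stopIfNot(length(electrodes) > 0L, "electrode subset must be non-empty")
  keys <- as.character(electrodes)
  stopIfNot(all(keys %in% rownames(psthCounts(m))),
            "electrode not present in the PSTH matrix")
  per <- rowSums(psthCounts(m))[keys]
  list(perElectrode = per, moduleMean = mean(per))
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test with midrank ties. The U statistic (number
#' of (x, y) pairs with x > y, ties counting one half) is computed from the
#' pooled ranks; the p-value uses the exact null distribution when
#' `length(x) + length(y) <= 16` and there are no ties, and the normal
#' approximation with tie and continuity corrections otherwise.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `U`, `pValue`, and `method` (`"exact"` or
#'   `"approximate"`).
#' @export
rankSumTest <- function(x, y) {
  stopIfNot(length(x) >= 1L && length(y) >= 1L, "both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (nx + ny <= 16L) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
  # degenerate pooled sample (all values tied): no evidence against the null
  if (!is.finite(p)) p <- 1
  list(U = unname(U), pValue = p,
       method = if (exact) "exact" else "approximate")
}

#' Per-electrode PSTH differences between two tests
#'
#' @param before,after [PSTHMatrix-class] objects from two test stimulations
#'   of the same recording site.
#' @param electrodes electrode ids to difference over.
#' @return named numeric vector `meanPSTH(after) - meanPSTH(before)` per
#'   electrode.
#' @export
psthDifferences <- function(before, after, electrodes) {
  b <- meanPSTH(before, electrodes)$perElectrode
  a <- meanPSTH(after, electrodes)$perElectrode
  a - b
}

#' Classify tetanus-induced plasticity
#'
#' Compares the spontaneous per-electrode change PRE = meanPSTH(test2) -
#' meanPSTH(test1) against the tetanus-induced change POST = meanPSTH(test3)
#' - meanPSTH(test2) with a two-sided rank-sum test. When p < alpha the
#' outcome is potentiation if the POST median exceeds the PRE median and
#' depression if it is lower; otherwise no effect. The averaged magnitude —
#' the mean |POST difference| over the module's electrodes — is reported only
#' for significant outcomes, as it summarizes experiments where a tetanus
#' effect was found.
#'
#' @param preDiffs,postDiffs named per-electrode difference vectors, paired
#'   by electrode id (same names, same order).
#' @param alpha significance level (0.05 by default, two-sided).
#' @param excluded electrode ids dropped upstream (e.g. silent in all tests),
#'   recorded in the result.
#' @return a [PlasticityResult-class].
#' @export
classifyPlasticity <- function(preDiffs, postDiffs, alpha = 0.05,
                               excluded = integer(0)) {
  if (!identical(names(preDiffs), names(postDiffs)))
    stop("preDiffs and postDiffs must cover the same electrodes in the same order",
         call. = FALSE)
  rs <- rankSumTest(preDiffs, postDiffs)
  label <- "none"
  if (rs$pValue < alpha) {
    label <- if (stats::median(postDiffs) > stats::median(preDiffs))
      "potentiation" else "depression"
  }
  new("PlasticityResult", preDiffs = preDiffs, postDiffs = postDiffs,
      statistic = rs$U, pValue = rs$pValue, alpha = alpha, label = label,
      avgMagnitude = if (label == "none") NA_real_ else mean(abs(postDiffs)),
      excluded = as.integer(excluded))
}
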
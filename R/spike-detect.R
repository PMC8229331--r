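#' Robust noise estimate of a voltage trace
#'
#' Median-based scale estimate of the noise: `median(|x|) / 0.6745`, the
#' robust Gaussian standard-deviation estimator used to set the detection
#' threshold. Spikes are sparse, so they barely move the median, unlike the
#' sample SD.
#'
#' @param trace numeric voltage vector (uV).
#' @return estimated noise SD in uV.
#' @examples
#' noiseSigma(rnorm(20000, sd = 5)) # close to 5
#' @export
noiseSigma <- function(trace) {
  if (!length(trace)) stop("empty trace", call. = FALSE)
  stats::median(abs(trace)) / 0.6745
}

#' Spike-detection parameters
#'
#' @param kSigma threshold multiplier: the threshold is
#'   `kSigma x noiseSigma(trace)`.
#' @param deadTime refractory suppression after an accepted crossing, ms.
#' @param polarity `"negative"`, `"positive"`, or `"both"` threshold crossings.
#' @param align `"extremum"` (spike time at the absolute extremum within 1 ms
#'   after the crossing; amplitude-jitter free) or `"crossing"`.
#' @return a named list of validated parameters.
#' @export
detectionParams <- function(kSigma = 8, deadTime = 1,
                            polarity = c("negative", "positive", "both"),
                            align = c("extremum", "crossing")) {
  stopIfNot(kSigma > 0, "kSigma must be > 0")
  stopIfNot(deadTime >= 0, "deadTime must be >= 0")
  list(kSigma = kSigma, deadTime = deadTime,
       polarity = match.arg(polarity), align = match.arg(align))
}

# crossings of a single threshold sign on one trace; returns sample indices
crossingIndices <- function(x, thr, sign) {
  if (sign < 0) {
    below <- x < -thr
    which(below & !c(FALSE, below[-length(below)]))
  } else {
    above <- x > thr
    which(above & !c(FALSE, above[-length(above)]))
  }
}

# detect on one trace; returns data.frame(time_s, amplitude_uV)
detectTrace <- function(x, fs, params) {
  sigma <- noiseSigma(x)
  if (sigma == 0) return(data.frame(time_s = numeric(0), amplitude_uV = numeric(0)))
  thr <- params$kSigma * sigma
  idx <- switch(params$polarity,
                negative = crossingIndices(x, thr, -1),
                positive = crossingIndices(x, thr, +1),
                both = sort(c(crossingIndices(x, thr, -1),
                              crossingIndices(x, thr, +1))))
  if (!length(idx)) return(data.frame(time_s = numeric(0), amplitude_uV = numeric(0)))
  span <- max(1L, round(0.001 * fs))   # 1 ms alignment window
  dead <- round(msToS(params$deadTime) * fs)
  keep <- logical(length(idx))
  last <- -Inf
  for (i in seq_along(idx)) {
    if (idx[i] - last > dead) { keep[i] <- TRUE; last <- idx[i] }
  }
  idx <- idx[keep]
  n <- length(x)
  time_s <- numeric(length(idx)); amp <- numeric(length(idx))
  for (i in seq_along(idx)) {
    win <- idx[i]:min(n, idx[i] + span)
    ext <- win[which.max(abs(x[win]))]
    if (params$align == "extremum") {
      time_s[i] <- (ext - 1L) / fs
    } else {
      time_s[i] <- (idx[i] - 1L) / fs
    }
    amp[i] <- x[ext]
  }
  data.frame(time_s = time_s, amplitude_uV = amp)
}

#' Threshold spike detection on raw traces
#'
#' Per electrode, the detection threshold is `kSigma` times the median-based
#' noise estimate ([noiseSigma()]). An event is registered where the trace
#' crosses the (negative and/or positive) threshold; the spike time is the
#' absolute extremum within 1 ms after the crossing, the amplitude is the
#' extremum value, and subsequent crossings within `deadTime` are suppressed.
#' Events from all electrodes are merged into one time-sorted
#' [SpikeTable-class].
#'
#' Detected spike times are scale-equivariant: multiplying a trace by any
#' positive constant leaves them unchanged, because threshold and noise
#' estimate scale together.
#'
#' @param raw a [RawSignalSet-class].
#' @param params a [detectionParams()] list.
#' @return a [SpikeTable-class].
#' @export
detectSpikes <- function(raw, params = detectionParams()) {
  stopifnot(is(raw, "RawSignalSet"))
  validObject(raw)
  fs <- raw@meta@samplingRate
  if (fs < 2000)
    stop("sampling rate below 2 kHz: insufficient resolution for 1 ms alignment",
         call. = FALSE)
  el <- integer(0); tm <- numeric(0); am <- numeric(0)
  for (id in names(raw@samples)) {
    d <- detectTrace(raw@samples[[id]], fs, params)
    if (nrow(d)) {
      el <- c(el, rep(as.integer(id), nrow(d)))
      tm <- c(tm, d$time_s)
      am <- c(am, d$amplitude_uV)
    }
  }
  spikeTable(raw@meta, raw@layout, el, tm, am)
}
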
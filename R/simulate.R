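# Statistical generator for the two-module network. Not a biophysical model:
# it reproduces the statistics the estimators consume (burst envelopes with a
# well-defined rate peak, peak-to-peak propagation delays, Poisson evoked
# counts, Gaussian-noise raw traces) with ground truth for every stage.

#' Build a simulator configuration
#'
#' Defaults describe a mature (25 DIV) culture with Fish-type microchannels:
#' Source network bursts at 20/min with envelope widths of 141 +/- 65 ms
#' (truncated at 20 ms), per-electrode peak rate 100 spikes/s, background
#' 0.5 spikes/s per electrode, forward propagation probability 0.25 with a
#' 50 +/- 10 ms peak-to-peak delay, and no autonomous Target bursting (the
#' connection is unidirectional; autonomous Target activity and backward
#' propagation are available via `targetAutonomousRate` / `pBackward`).
#' Evoked responses default to 5 expected spikes per Target electrode per
#' stimulus at unit weight, latency 30 +/- 15 ms, with a Source retrograde
#' share of 0.8; a tetanus multiplies the weight by `tetanusEffect`.
#'
#' @param seed integer RNG seed.
#' @param duration recording length, s.
#' @param chipType `"fish"` or `"octopus"`.
#' @param burstRate Source burst rate, bursts/min.
#' @param burstDurationMean,burstDurationSd envelope width, ms.
#' @param intraBurstPeakRate per-electrode peak rate, spikes/s.
#' @param backgroundRate background rate, spikes/s per electrode.
#' @param pForward,pBackward propagation probabilities.
#' @param targetAutonomousRate autonomous Target burst rate, bursts/min.
#' @param propagationDelayMean,propagationDelaySd peak delay, ms.
#' @param evokedWeight synaptic efficacy scaling Target evoked counts.
#' @param evokedLatencyMean,evokedLatencySd evoked latency, ms.
#' @param tetanusEffect multiplicative weight change of a tetanus.
#' @param baseCount expected evoked spikes/electrode/stimulus at weight 1.
#' @param retroFraction Source retrograde share of `baseCount`.
#' @param noiseSigma raw-trace noise SD, uV.
#' @param spikeAmplitude raw-trace spike negative-peak amplitude, uV.
#' @return a [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 1, duration = 60)
#' sim <- simulateSpontaneous(cfg)
#' sim$spikes
#' @export
simConfig <- function(seed = 1L, duration = 600, chipType = "fish",
                      burstRate = 20, burstDurationMean = 141,
                      burstDurationSd = 65, intraBurstPeakRate = 100,
                      backgroundRate = 0.5, pForward = 0.25, pBackward = 0,
                      targetAutonomousRate = 0, propagationDelayMean = 50,
                      propagationDelaySd = 10, evokedWeight = 1,
                      evokedLatencyMean = 30, evokedLatencySd = 15,
                      tetanusEffect = 1.5, baseCount = 5, retroFraction = 0.8,
                      noiseSigma = 5, spikeAmplitude = 50) {
  new("SimConfig", seed = as.integer(seed), duration = duration,
      chipType = chipType, burstRate = burstRate,
      burstDurationMean = burstDurationMean, burstDurationSd = burstDurationSd,
      intraBurstPeakRate = intraBurstPeakRate, backgroundRate = backgroundRate,
      pForward = pForward, pBackward = pBackward,
      targetAutonomousRate = targetAutonomousRate,
      propagationDelayMean = propagationDelayMean,
      propagationDelaySd = propagationDelaySd, evokedWeight = evokedWeight,
      evokedLatencyMean = evokedLatencyMean, evokedLatencySd = evokedLatencySd,
      tetanusEffect = tetanusEffect, baseCount = baseCount,
      retroFraction = retroFraction, noiseSigma = noiseSigma,
      spikeAmplitude = spikeAmplitude)
}

#' @rdname simConfig
#' @param config a [SimConfig-class].
#' @export
setSimSeed <- function(config, seed) {
  config@seed <- as.integer(seed)
  validObject(config)
  config
}

# envelope: linear rise over the first 20% of the width, exponential decay
# with tau = 0.8 w / 3 over the rest; unimodal peak at 0.2 w
riseFrac <- 0.2

envelopeIntegral <- function(w) {
  tau <- (1 - riseFrac) * w / 3
  riseFrac * w / 2 + tau * (1 - exp(-3))
}

# inverse-CDF sampling of spike offsets (s) under the envelope of width w (s)
sampleEnvelopeTimes <- function(n, w) {
  if (n == 0L) return(numeric(0))
  tau <- (1 - riseFrac) * w / 3
  I <- envelopeIntegral(w)
  pRise <- (riseFrac * w / 2) / I
  branch <- stats::runif(n) < pRise
  v <- stats::runif(n)
  t <- numeric(n)
  t[branch] <- riseFrac * w * sqrt(v[branch])
  t[!branch] <- riseFrac * w - tau * log(1 - v[!branch] * (1 - exp(-3)))
  t
}

# burst scaffolds: Poisson onsets thinned by a post-burst refractory gap
# (a module cannot start a new network burst while one is running or during
# the immediate recovery), truncated-normal widths; bursts that do not fit
# inside [0, duration] are discarded
burstRefractory <- 0.3   # s between a burst offset and the next onset

drawBurstScaffold <- function(ratePerMin, config) {
  dur <- config@duration
  n <- stats::rpois(1L, ratePerMin / 60 * dur)
  if (n == 0L)
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      peak_time = numeric(0), width = numeric(0)))
  onset <- sort(stats::runif(n, 0, dur))
  width <- rtruncnorm(n, msToS(config@burstDurationMean),
                      msToS(config@burstDurationSd), lower = 0.02)
  keep <- logical(n)
  lastOffset <- -Inf
  for (i in seq_len(n)) {
    if (onset[i] >= lastOffset + burstRefractory && onset[i] + width[i] <= dur) {
      keep[i] <- TRUE
      lastOffset <- onset[i] + width[i]
    }
  }
  data.frame(onset = onset[keep], offset = (onset + width)[keep],
             peak_time = (onset + riseFrac * width)[keep], width = width[keep])
}

# spikes for one module's bursts on the given electrodes
emitBurstSpikes <- function(bursts, electrodes, config) {
  el <- integer(0); tm <- numeric(0)
  for (i in seq_len(nrow(bursts))) {
    w <- bursts$width[i]
    mu <- config@intraBurstPeakRate * envelopeIntegral(w)
    counts <- stats::rpois(length(electrodes), mu)
    if (sum(counts) == 0L) next
    el <- c(el, rep(electrodes, counts))
    tm <- c(tm, bursts$onset[i] + sampleEnvelopeTimes(sum(counts), w))
  }
  list(electrode = el, time = tm)
}

emitBackground <- function(electrodes, rate, duration) {
  counts <- stats::rpois(length(electrodes), rate * duration)
  list(electrode = rep(electrodes, counts),
       time = stats::runif(sum(counts), 0, duration))
}

#' Simulate spontaneous activity of the two-module network
#'
#' Source network bursts arise as a Poisson process; each burst emits spikes
#' per Source-chamber electrode as an inhomogeneous Poisson process under a
#' rise-decay envelope. With probability `pForward` a Target burst follows at
#' a truncated-normal peak-to-peak delay; independent Target bursts (rate
#' `targetAutonomousRate`) back-propagate with probability `pBackward`.
#' Homogeneous background spikes cover all active electrodes. All draws come
#' from the seeded generator, so identical seed + config give identical
#' output; spike times are reported at 1 us resolution.
#'
#' @param config a [SimConfig-class].
#' @return list with `spikes` (a [SpikeTable-class]) and `truth`
#'   (a [SimTruth-class]).
#' @export
simulateSpontaneous <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    layout <- defaultLayout(config@chipType)
    srcEl <- moduleElectrodes(layout, "source")
    tgtEl <- moduleElectrodes(layout, "target")
    activeEl <- layoutTable(layout)$electrode[layoutTable(layout)$region != "reference"]
    dur <- config@duration

    src <- drawBurstScaffold(config@burstRate, config)
    src$origin <- rep("autonomous", nrow(src))

    # forward propagation: delayed Target partner for a subset of Source bursts
    fwdSel <- which(stats::runif(nrow(src)) < config@pForward)
    fwd <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak_time = numeric(0), width = numeric(0),
                      src_row = integer(0), delay_ms = numeric(0))
    if (length(fwdSel)) {
      delay <- rtruncnorm(length(fwdSel), msToS(config@propagationDelayMean),
                          msToS(config@propagationDelaySd), lower = 0)
      wid <- rtruncnorm(length(fwdSel), msToS(config@burstDurationMean),
                        msToS(config@burstDurationSd), lower = 0.02)
      peak <- src$peak_time[fwdSel] + delay
      onset <- peak - riseFrac * wid
      keep <- onset >= 0 & onset + wid <= dur
      fwd <- data.frame(onset = onset[keep], offset = (onset + wid)[keep],
                        peak_time = peak[keep], width = wid[keep],
                        src_row = fwdSel[keep], delay_ms = sToMs(delay[keep]))
    }

    tgtAuto <- drawBurstScaffold(config@targetAutonomousRate, config)

    # backward propagation: delayed Source partner for autonomous Target bursts
    bwdSel <- which(stats::runif(nrow(tgtAuto)) < config@pBackward)
    bwd <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak_time = numeric(0), width = numeric(0),
                      tgt_row = integer(0), delay_ms = numeric(0))
    if (length(bwdSel)) {
      delay <- rtruncnorm(length(bwdSel), msToS(config@propagationDelayMean),
                          msToS(config@propagationDelaySd), lower = 0)
      wid <- rtruncnorm(length(bwdSel), msToS(config@burstDurationMean),
                        msToS(config@burstDurationSd), lower = 0.02)
      peak <- tgtAuto$peak_time[bwdSel] + delay
      onset <- peak - riseFrac * wid
      keep <- onset >= 0 & onset + wid <= dur
      bwd <- data.frame(onset = onset[keep], offset = (onset + wid)[keep],
                        peak_time = peak[keep], width = wid[keep],
                        tgt_row = bwdSel[keep], delay_ms = sToMs(delay[keep]))
    }

    # assemble per-module burst tables sorted by onset, remembering identities
    srcAll <- rbind(src[c("onset", "offset", "peak_time", "width")],
                    bwd[c("onset", "offset", "peak_time", "width")])
    srcKey <- c(paste0("a", seq_len(nrow(src))), paste0("b", seq_len(nrow(bwd))))
    oS <- order(srcAll$onset)
    srcAll <- srcAll[oS, , drop = FALSE]; srcKey <- srcKey[oS]

    tgtAll <- rbind(fwd[c("onset", "offset", "peak_time", "width")],
                    tgtAuto[c("onset", "offset", "peak_time", "width")])
    tgtKey <- c(paste0("f", seq_len(nrow(fwd))), paste0("t", seq_len(nrow(tgtAuto))))
    oT <- order(tgtAll$onset)
    tgtAll <- tgtAll[oT, , drop = FALSE]; tgtKey <- tgtKey[oT]

    events <- data.frame(source_idx = integer(0), target_idx = integer(0),
                         direction = character(0), delay_ms = numeric(0))
    if (nrow(fwd))
      events <- rbind(events, data.frame(
        source_idx = match(paste0("a", fwd$src_row), srcKey),
        target_idx = match(paste0("f", seq_len(nrow(fwd))), tgtKey),
        direction = "forward", delay_ms = fwd$delay_ms))
    if (nrow(bwd))
      events <- rbind(events, data.frame(
        source_idx = match(paste0("b", seq_len(nrow(bwd))), srcKey),
        target_idx = match(paste0("t", bwd$tgt_row), tgtKey),
        direction = "backward", delay_ms = bwd$delay_ms))
    rownames(events) <- NULL

    sp1 <- emitBurstSpikes(srcAll, srcEl, config)
    sp2 <- emitBurstSpikes(tgtAll, tgtEl, config)
    bg <- emitBackground(activeEl, config@backgroundRate, dur)

    el <- c(sp1$electrode, sp2$electrode, bg$electrode)
    tm <- pmin(round(c(sp1$time, sp2$time, bg$time), 6), dur)
    meta <- recordingMeta(duration = dur, chipType = config@chipType,
                          label = sprintf("simulated spontaneous (seed %d)", config@seed))
    spikes <- spikeTable(meta, layout, el, tm)
    truth <- new("SimTruth",
                 sourceBursts = srcAll[c("onset", "offset", "peak_time")],
                 targetBursts = tgtAll[c("onset", "offset", "peak_time")],
                 propagationEvents = events,
                 evokedCounts = matrix(numeric(0), 0, 0))
    list(spikes = spikes, truth = truth)
  })
}

#' Simulate stimulus-evoked responses
#'
#' For each test stimulus, every Target-chamber electrode emits
#' `Poisson(weight x baseCount)` spikes at truncated-normal latencies inside
#' the chip's analysis window, and every Source-chamber electrode emits
#' `Poisson(retroFraction x baseCount)` retrograde spikes (independent of
#' `weight`: the probe measures the Source-to-Target efficacy). Latencies
#' before 10 ms post-stimulus are suppressed, mirroring artifact blanking.
#' Background spikes cover all active electrodes.
#'
#' @param config a [SimConfig-class].
#' @param log a test-protocol [StimulusLog-class] (a tetanus log is rejected;
#'   apply [applyTetanus()] to the weight between tests instead).
#' @param weight synaptic efficacy; defaults to `config@evokedWeight`.
#' @return list with `spikes` (a [SpikeTable-class]) and `truth`
#'   (a [SimTruth-class] whose `evokedCounts` holds the intended
#'   per-stimulus, per-electrode spike counts).
#' @export
simulateEvoked <- function(config, log, weight = config@evokedWeight) {
  validObject(config); validObject(log)
  if (log@protocol == "tetanus")
    stop("tetanus logs are not test stimulations; apply applyTetanus() to the weight instead",
         call. = FALSE)
  stopIfNot(weight >= 0, "weight must be >= 0")
  withSeed(config@seed, {
    layout <- defaultLayout(config@chipType)
    srcEl <- moduleElectrodes(layout, "source")
    tgtEl <- moduleElectrodes(layout, "target")
    activeEl <- layoutTable(layout)$electrode[layoutTable(layout)$region != "reference"]
    win <- defaultWindow(config@chipType)
    lo <- max(10, win[1]); hi <- win[2]
    nStim <- length(log@stimTimes)
    dur <- max(log@stimTimes) + 2

    drawModule <- function(electrodes, mu) {
      counts <- matrix(stats::rpois(nStim * length(electrodes), mu),
                       nrow = nStim, dimnames = list(NULL, electrodes))
      tot <- sum(counts)
      lat <- rtruncnorm(tot, config@evokedLatencyMean, config@evokedLatencySd,
                        lower = lo, upper = hi)
      stimOf <- rep(rep(seq_len(nStim), length(electrodes)), counts)
      elOf <- rep(rep(electrodes, each = nStim), counts)
      list(counts = counts, electrode = elOf,
           time = log@stimTimes[stimOf] + msToS(lat))
    }

    tgt <- drawModule(tgtEl, weight * config@baseCount)
    src <- drawModule(srcEl, config@retroFraction * config@baseCount)
    bg <- emitBackground(activeEl, config@backgroundRate, dur)

    el <- c(tgt$electrode, src$electrode, bg$electrode)
    tm <- pmin(round(c(tgt$time, src$time, bg$time), 6), dur)
    meta <- recordingMeta(duration = dur, chipType = config@chipType,
                          label = sprintf("simulated evoked %s (seed %d)",
                                          log@protocol, config@seed))
    spikes <- spikeTable(meta, layout, el, tm)
    evoked <- cbind(src$counts, tgt$counts)
    evoked <- evoked[, order(as.integer(colnames(evoked))), drop = FALSE]
    truth <- new("SimTruth",
                 sourceBursts = data.frame(onset = numeric(0), offset = numeric(0),
                                           peak_time = numeric(0)),
                 targetBursts = data.frame(onset = numeric(0), offset = numeric(0),
                                           peak_time = numeric(0)),
                 propagationEvents = data.frame(source_idx = integer(0),
                                                target_idx = integer(0),
                                                direction = character(0),
                                                delay_ms = numeric(0)),
                 evokedCounts = evoked)
    list(spikes = spikes, truth = truth)
  })
}

#' Apply a tetanus to the synaptic efficacy
#'
#' Pure function returning `weight x config@tetanusEffect`: the tetanus is
#' modeled phenomenologically as a multiplicative change of the evoked
#' response gain (>1 potentiation, <1 depression, 1 no effect) — exactly the
#' quantity the PSTH readout measures.
#'
#' @param weight current efficacy (>= 0).
#' @param config a [SimConfig-class].
#' @return the post-tetanus efficacy.
#' @export
applyTetanus <- function(weight, config) {
  stopIfNot(weight >= 0, "weight must be >= 0")
  weight * config@tetanusEffect
}

# biphasic extracellular spike template, ~1 ms, negative peak normalized to -1
biphasicTemplate <- function(samplingRate) {
  t <- seq(0, 1e-3, by = 1 / samplingRate)
  neg <- 0.3e-3
  w <- ifelse(t < neg, -sin(pi * t / neg), 0.35 * sin(pi * (t - neg) / (1e-3 - neg)))
  w / abs(min(w))
}

#' Synthesize raw voltage traces from a spike table
#'
#' Each electrode's trace is Gaussian noise of SD `noiseSigma` plus a
#' biphasic ~1 ms spike template centered (negative peak) at each spike time,
#' scaled by the event's amplitude when present and by
#' `config@spikeAmplitude` otherwise; overlapping templates sum linearly.
#' Deterministic under the config seed.
#'
#' @param spikes a [SpikeTable-class].
#' @param config a [SimConfig-class].
#' @return a [RawSignalSet-class] covering all active electrodes.
#' @export
synthesizeRaw <- function(spikes, config) {
  validObject(spikes)
  meta <- spikes@meta
  ev <- spikeEvents(spikes)
  if (nrow(ev) && any(ev$time_s > meta@duration))
    stop("spike beyond recording duration", call. = FALSE)
  withSeed(config@seed, {
    fs <- meta@samplingRate
    n <- round(meta@duration * fs)
    tmpl <- biphasicTemplate(fs)
    peakAt <- which.min(tmpl)
    tb <- layoutTable(spikes@layout)
    activeEl <- tb$electrode[tb$region != "reference"]
    samples <- lapply(activeEl, function(e) {
      x <- if (config@noiseSigma > 0) stats::rnorm(n, 0, config@noiseSigma) else numeric(n)
      rows <- which(ev$electrode == e)
      for (i in rows) {
        amp <- ev$amplitude_uV[i]
        if (is.na(amp)) amp <- config@spikeAmplitude
        center <- round(ev$time_s[i] * fs) + 1L
        idx <- center - peakAt + seq_along(tmpl)
        ok <- idx >= 1L & idx <= n
        x[idx[ok]] <- x[idx[ok]] + amp * tmpl[ok]
      }
      x
    })
    names(samples) <- as.character(activeEl)
    new("RawSignalSet", meta = meta, layout = spikes@layout, samples = samples)
  })
}

#' Generate stimulation protocols
#'
#' `makeTestProtocol()` builds a low-frequency probe train: `nStimuli`
#' pulses with inter-stimulus intervals drawn uniformly from `isiRange`.
#' `makeTetanusProtocol()` builds the conditioning stimulation: exactly 20
#' trains of 10 pulses, 50 ms between pulses and 5 s between trains
#' (200 pulses). Default stimulation sites are the Source-end electrodes of
#' four adjacent microchannels.
#'
#' @param nStimuli number of test pulses (60 or 300 in a standard session).
#' @param isiRange inter-stimulus interval range, s.
#' @param seed RNG seed for the ISI draws.
#' @param protocol which test label to mark the log with.
#' @param stimElectrodes stimulated electrode ids.
#' @param startTime time of the first pulse, s.
#' @return a [StimulusLog-class].
#' @export
makeTestProtocol <- function(nStimuli = 60, isiRange = c(1, 5), seed = 1L,
                             protocol = "test1",
                             stimElectrodes = c(19L, 22L, 25L, 28L),
                             startTime = 1) {
  stopIfNot(protocol %in% c("test1", "test2", "test3"),
            "protocol must be a test protocol")
  times <- withSeed(seed, {
    isi <- stats::runif(nStimuli - 1L, isiRange[1], isiRange[2])
    round(startTime + cumsum(c(0, isi)), 6)
  })
  stimulusLog(times, stimElectrodes, protocol = protocol, isiRange = isiRange)
}

#' @rdname makeTestProtocol
#' @export
makeTetanusProtocol <- function(stimElectrodes = c(19L, 22L, 25L, 28L),
                                startTime = 1) {
  train <- rep(seq_len(20L), each = 10L) - 1L
  pulse <- rep(seq_len(10L), times = 20L) - 1L
  times <- startTime + train * (5 + 9 * 0.05) + pulse * 0.05
  stimulusLog(round(times, 6), stimElectrodes, protocol = "tetanus")
}

#' Simulate a full plasticity-induction experiment
#'
#' Produces the test1 / test2 / test3 sequence around a tetanus: test1 and
#' test2 probe the baseline efficacy (their difference measures spontaneous
#' drift), the tetanus multiplies the efficacy by `config@tetanusEffect`,
#' and test3 probes the changed efficacy. Each test gets its own protocol
#' and an independent sub-seed derived from the config seed by fixed offsets.
#'
#' @param config a [SimConfig-class].
#' @param nStimuli test pulses per probe train.
#' @return list of `test1`, `test2`, `test3` (each `list(spikes, log, truth)`)
#'   plus `weights`, the efficacy in force during each test.
#' @export
simulatePlasticityExperiment <- function(config, nStimuli = 60) {
  w <- c(config@evokedWeight, config@evokedWeight,
         applyTetanus(config@evokedWeight, config))
  out <- list()
  for (i in 1:3) {
    log <- makeTestProtocol(nStimuli, seed = config@seed + 1000L + i,
                            protocol = paste0("test", i))
    sim <- simulateEvoked(setSimSeed(config, config@seed + 2000L * i), log, w[i])
    out[[paste0("test", i)]] <- list(spikes = sim$spikes, log = log,
                                     truth = sim$truth)
  }
  out$weights <- w
  out
}
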
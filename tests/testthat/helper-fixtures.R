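# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, enumeration, brute force) and never call the code paths they check.

fishLayout <- defaultLayout("fish")

makeMeta <- function(duration = 10, chipType = "fish", samplingRate = 20000) {
  recordingMeta(samplingRate = samplingRate, duration = duration,
                chipType = chipType)
}

makeSpikes <- function(electrode, time_s, duration = 10, amplitude = NULL,
                       chipType = "fish") {
  spikeTable(makeMeta(duration, chipType), fishLayout, electrode, time_s,
             amplitude)
}

# random valid spike table; times/amplitudes snapped to the file format's
# fixed decimal grid so text round trips are value-exact
snapDec <- function(x, digits) as.numeric(sprintf("%.*f", digits, x))

randomSpikeTable <- function(n, duration = 10, withAmp = TRUE) {
  ids <- layoutTable(fishLayout)$electrode
  ids <- ids[seq_len(59)]   # active electrodes
  makeSpikes(sample(ids, n, replace = TRUE),
             snapDec(runif(n, 0, duration), 6), duration,
             if (withAmp) snapDec(runif(n, -80, -20), 3) else NULL)
}

# brute-force PSTH: per electrode, per stimulus, per bin triple loop
brutePSTH <- function(spikes, log, window, bin = 2) {
  ev <- spikeEvents(spikes)
  tb <- layoutTable(electrodeLayout(spikes))
  electrodes <- tb$electrode[tb$region != "reference"]
  nb <- as.integer((window[2] - window[1]) / bin)
  raw <- matrix(0L, nrow = length(electrodes), ncol = nb,
                dimnames = list(as.character(electrodes), NULL))
  for (ei in seq_along(electrodes)) {
    t <- ev$time_s[ev$electrode == electrodes[ei]]
    for (s in log@stimTimes) {
      lat <- (t - s) * 1000
      for (b in seq_len(nb)) {
        lo <- window[1] + (b - 1) * bin
        raw[ei, b] <- raw[ei, b] + sum(lat >= lo & lat < lo + bin)
      }
    }
  }
  raw
}

# exhaustive two-sided Mann-Whitney p by label-permutation enumeration
# (no-tie samples only); same doubling convention as the exact test
enumRankSumP <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  stopifnot(!anyDuplicated(pool))
  u <- sum(outer(x, y, ">"))
  sets <- utils::combn(length(pool), nx)
  Ud <- apply(sets, 2, function(ix) sum(outer(pool[ix], pool[-ix], ">")))
  min(1, 2 * min(mean(Ud <= u), mean(Ud >= u)))
}

# brute-force minimum-total-|delay| matching within a window, by enumeration
# over all injective assignments (small instances only)
bruteBestMatching <- function(sp, tp, window = 200) {
  ns <- length(sp); nt <- length(tp)
  best <- list(cost = Inf, n = 0L)
  # enumerate subsets of sources and all injective maps into targets
  score <- function(sIdx, tIdx) sum(abs((tp[tIdx] - sp[sIdx]) * 1000))
  feasible <- function(sIdx, tIdx)
    all(abs((tp[tIdx] - sp[sIdx]) * 1000) <= window)
  k <- 0
  for (m in seq_len(min(ns, nt))) {
    sSets <- utils::combn(ns, m, simplify = FALSE)
    tSets <- utils::combn(nt, m, simplify = FALSE)
    for (ss in sSets) for (ts in tSets) {
      perms <- permMatrix(m)
      for (p in seq_len(nrow(perms))) {
        ti <- ts[perms[p, ]]
        if (!feasible(ss, ti)) next
        cost <- score(ss, ti)
        if (m > best$n || (m == best$n && cost < best$cost))
          best <- list(cost = cost, n = m)
      }
    }
  }
  best
}

permMatrix <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- permMatrix(m - 1L)
  out <- NULL
  for (i in seq_len(m)) {
    rest <- setdiff(seq_len(m), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# greedy nearest match of detected to true spike times within tol (s);
# returns number of matched pairs
matchSpikeTimes <- function(truth, detected, tol = 1e-3) {
  if (!length(truth) || !length(detected)) return(0L)
  usedD <- logical(length(detected))
  matched <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[usedD] <- Inf
    i <- which.min(d)
    if (d[i] <= tol) { usedD[i] <- TRUE; matched <- matched + 1L }
  }
  matched
}
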
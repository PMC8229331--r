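test_that("degenerate configurations produce empty structures", {
  cfg <- simConfig(seed = 1, duration = 60, pForward = 0,
                   targetAutonomousRate = 0)
  sim <- simulateSpontaneous(cfg)
  expect_equal(nrow(sim$truth@targetBursts), 0L)
  expect_equal(nrow(sim$truth@propagationEvents), 0L)

  cfg0 <- simConfig(seed = 1, duration = 60, burstRate = 0,
                    backgroundRate = 0, targetAutonomousRate = 0)
  expect_equal(nrow(spikeEvents(simulateSpontaneous(cfg0)$spikes)), 0L)
})

test_that("source burst counts follow the Poisson law", {
  # 6 bursts/min over 600 s: expect 60 +/- 3 sqrt(60)
  counts <- vapply(1:5, function(s) {
    cfg <- simConfig(seed = s, duration = 600, burstRate = 6,
                     backgroundRate = 0, pForward = 0)
    nrow(simulateSpontaneous(cfg)$truth@sourceBursts)
  }, numeric(1))
  expect_true(all(abs(counts - 60) <= 3 * sqrt(60)))
})

test_that("simulation output is deterministic under seed and config", {
  cfg <- simConfig(seed = 99, duration = 120)
  a <- simulateSpontaneous(cfg)
  b <- simulateSpontaneous(cfg)
  expect_identical(spikeEvents(a$spikes), spikeEvents(b$spikes))
  expect_identical(a$truth@sourceBursts, b$truth@sourceBursts)
  expect_identical(a$truth@propagationEvents, b$truth@propagationEvents)
})

test_that("ground truth is internally consistent across seeds", {
  for (s in 1:5) {
    cfg <- simConfig(seed = s, duration = 200, pForward = 0.4,
                     targetAutonomousRate = 3, pBackward = 0.3)
    tr <- simulateSpontaneous(cfg)$truth
    ev <- tr@propagationEvents
    expect_true(all(ev$source_idx >= 1 & ev$source_idx <= nrow(tr@sourceBursts)))
    expect_true(all(ev$target_idx >= 1 & ev$target_idx <= nrow(tr@targetBursts)))
    expect_true(all(ev$delay_ms > 0))
    expect_lte(sum(ev$direction == "forward"), nrow(tr@sourceBursts))
    # forward events: target peak follows its source peak by the stated delay
    fwd <- ev[ev$direction == "forward", ]
    if (nrow(fwd)) {
      gap <- tr@targetBursts$peak_time[fwd$target_idx] -
        tr@sourceBursts$peak_time[fwd$source_idx]
      expect_equal(gap * 1000, fwd$delay_ms, tolerance = 1e-6)
    }
  }
})

test_that("realized forward propagation converges to pForward", {
  # binomial law: over a long recording the realized fraction sits within
  # 3 binomial SDs of the configured probability
  cfg <- simConfig(seed = 5, duration = 1800, burstRate = 20, pForward = 0.3,
                   backgroundRate = 0)
  tr <- simulateSpontaneous(cfg)$truth
  n <- nrow(tr@sourceBursts)
  frac <- sum(tr@propagationEvents$direction == "forward") / n
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n) + 0.01)
})

test_that("evoked responses follow the configured Poisson counts", {
  log <- makeTestProtocol(60, seed = 11)
  cfg <- simConfig(seed = 2, backgroundRate = 0)

  # weight 0: no Target spikes at all
  sim0 <- simulateEvoked(cfg, log, weight = 0)
  tgt <- moduleElectrodes(fishLayout, "target")
  expect_equal(sum(spikeEvents(sim0$spikes)$electrode %in% tgt), 0L)

  # weight 1, base 5, 60 stimuli: per-electrode totals within 300 +/- 3 sqrt(300)
  sim1 <- simulateEvoked(cfg, log, weight = 1)
  tot <- colSums(sim1$truth@evokedCounts[, as.character(tgt)])
  expect_true(all(abs(tot - 300) <= 3 * sqrt(300)))
  # realized spikes match the intended counts
  expect_equal(sum(spikeEvents(sim1$spikes)$electrode %in% tgt), sum(tot))

  # doubling the weight doubles the expected per-stimulus count
  sim2 <- simulateEvoked(setSimSeed(cfg, 3), log, weight = 2)
  tot2 <- colSums(sim2$truth@evokedCounts[, as.character(tgt)])
  expect_equal(mean(tot2) / mean(tot), 2, tolerance = 0.1)

  # tetanus logs are not test stimulations
  expect_error(simulateEvoked(cfg, makeTetanusProtocol()), "tetanus")
})

test_that("evoked latencies respect the blanking window", {
  log <- makeTestProtocol(30, seed = 4)
  cfg <- simConfig(seed = 6, backgroundRate = 0)
  sim <- simulateEvoked(cfg, log, weight = 1)
  ev <- spikeEvents(sim$spikes)
  stimIdx <- findInterval(ev$time_s, log@stimTimes)
  lat <- (ev$time_s - log@stimTimes[stimIdx]) * 1000
  expect_true(all(lat >= 10))
  expect_true(all(lat <= defaultWindow("fish")[2] + 1e-6))
})

test_that("applyTetanus is a pure multiplicative update", {
  cfg <- simConfig(tetanusEffect = 1.5)
  expect_equal(applyTetanus(1, cfg), 1.5)
  expect_equal(applyTetanus(2, simConfig(tetanusEffect = 1)), 2)
  cfgD <- simConfig(tetanusEffect = 0.5)
  expect_equal(applyTetanus(applyTetanus(1, cfgD), cfgD), 0.25)
})

test_that("raw synthesis embeds templates in Gaussian noise", {
  # no spikes, no noise -> all-zero traces
  cfg <- simConfig(seed = 1, noiseSigma = 0)
  quiet <- makeSpikes(integer(0), numeric(0), duration = 0.1)
  raw0 <- synthesizeRaw(quiet, cfg)
  expect_true(all(vapply(raw0@samples, function(x) all(x == 0), logical(1))))

  # one spike, no noise -> trace is the template at that offset
  one <- makeSpikes(1L, 0.05, duration = 0.1)
  raw1 <- synthesizeRaw(one, cfg)
  x <- raw1@samples[["1"]]
  expect_equal(min(x), -cfg@spikeAmplitude)
  expect_equal(which.min(x), round(0.05 * 20000) + 1L)
  expect_true(all(raw1@samples[["2"]] == 0))

  # median-based estimator recovers the noise SD on a noise-only trace
  cfgN <- simConfig(seed = 3, noiseSigma = 5)
  quiet1s <- makeSpikes(integer(0), numeric(0), duration = 1)
  rawN <- synthesizeRaw(quiet1s, cfgN)
  expect_equal(noiseSigma(rawN@samples[["1"]]), 5, tolerance = 0.05 * 5)

  # spikes beyond the recording are an error
  late <- spikeTable(makeMeta(1), fishLayout, 1L, 0.5)
  late@meta@duration <- 0.2   # force inconsistency
  expect_error(synthesizeRaw(late, cfg), "duration")
})

test_that("stimulation protocols have the prescribed structure", {
  tet <- makeTetanusProtocol()
  expect_length(tet@stimTimes, 200L)
  d <- diff(tet@stimTimes)
  within <- d[rep(c(rep(TRUE, 9), FALSE), 20)[-200]]
  between <- d[seq(10, 190, by = 10)]
  expect_true(all(abs(within - 0.05) < 1e-9))
  expect_true(all(abs(between - 5) < 1e-9))

  log <- makeTestProtocol(60, seed = 8)
  isi <- diff(log@stimTimes)
  expect_length(isi, 59L)
  expect_true(all(isi >= 1 & isi <= 5))
})
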
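srcIds <- moduleElectrodes(fishLayout, "source")

# one hand-built network burst: nPer spikes per electrode spread over
# [onset, onset + width], plus a 2-spike-per-electrode volley at 20% of the
# width so the instantaneous-rate peak is unambiguous
burstSpikes <- function(onset, width, nPer = 6, electrodes = srcIds) {
  el <- c(rep(electrodes, each = nPer), rep(electrodes, each = 2L))
  tm <- c(rep(onset + seq(0, width, length.out = nPer), times = length(electrodes)),
          rep(onset + 0.2 * width, 2L * length(electrodes)))
  list(electrode = el, time = tm)
}

test_that("population rate counts module spikes into bins", {
  empty <- makeSpikes(integer(0), numeric(0), duration = 1)
  expect_true(all(populationRate(empty, "source") == 0))

  # 10 spikes in one 50 ms bin
  st <- makeSpikes(rep(srcIds[1:5], 2), rep(0.42, 10), duration = 1)
  r <- populationRate(st, "source", bin = 50)
  expect_equal(r[9], 10)
  expect_equal(sum(r), 10)
  expect_true(all(r[-9] == 0))

  # sum equals the module spike count on random tables (target spikes ignored)
  for (s in 1:5) {
    set.seed(s)
    st <- randomSpikeTable(500, duration = 5)
    ev <- spikeEvents(st)
    expect_equal(sum(populationRate(st, "source", bin = 20)),
                 sum(ev$electrode %in% srcIds))
    expect_equal(sum(populationRate(st, "target", bin = 20)),
                 sum(ev$electrode %in% moduleElectrodes(fishLayout, "target")))
  }
})

test_that("a single simulated burst is detected and covers the true window", {
  b <- burstSpikes(1.0, 0.14)
  st <- makeSpikes(b$electrode, b$time, duration = 3)
  bs <- detectBursts(st, "source")
  tb <- burstTable(bs)
  expect_equal(nrow(tb), 1L)
  overlap <- min(tb$offset, 1.14) - max(tb$onset, 1.0)
  expect_gte(overlap / 0.14, 0.9)
  expect_true(tb$peak_time >= tb$onset && tb$peak_time <= tb$offset)
  expect_equal(tb$n_active, length(srcIds))

  expect_equal(nrow(burstTable(detectBursts(
    makeSpikes(integer(0), numeric(0)), "source"))), 0L)
})

test_that("bursts merge below the merge gap and split above it", {
  # two bursts 500 ms apart (> 100 ms gap): two detections
  b1 <- burstSpikes(1.0, 0.1); b2 <- burstSpikes(1.6, 0.1)
  st <- makeSpikes(c(b1$electrode, b2$electrode), c(b1$time, b2$time),
                   duration = 3)
  expect_equal(nrow(burstTable(detectBursts(st, "source"))), 2L)

  # 60 ms apart (< 100 ms): merged into one
  b2 <- burstSpikes(1.16, 0.1)
  st <- makeSpikes(c(b1$electrode, b2$electrode), c(b1$time, b2$time),
                   duration = 3)
  expect_equal(nrow(burstTable(detectBursts(st, "source"))), 1L)
})

test_that("sparse runs are rejected by electrode and duration minima", {
  # strong rate on only 2 electrodes: below minActiveElectrodes
  b <- burstSpikes(1.0, 0.1, nPer = 20, electrodes = srcIds[1:2])
  st <- makeSpikes(b$electrode, b$time, duration = 3)
  expect_equal(nrow(burstTable(detectBursts(st, "source"))), 0L)

  # all spikes within 5 ms: below minDuration
  st <- makeSpikes(srcIds, rep(1.0, 18) + seq(0, 0.005, length.out = 18),
                   duration = 3)
  expect_equal(nrow(burstTable(detectBursts(st, "source"))), 0L)
})

test_that("detected bursts are disjoint and sorted on simulator output", {
  for (s in 1:3) {
    sim <- simulateSpontaneous(simConfig(seed = s, duration = 120))
    tb <- burstTable(detectBursts(sim$spikes, "source"))
    expect_false(is.unsorted(tb$onset))
    if (nrow(tb) > 1L)
      expect_true(all(tb$onset[-1] >= tb$offset[-nrow(tb)]))
  }
})

test_that("burst peak time is robust to sparse background spiking", {
  set.seed(21)
  deltas <- vapply(1:8, function(s) {
    b <- burstSpikes(1.0, 0.14, nPer = 8)
    clean <- makeSpikes(b$electrode, b$time, duration = 3)
    p0 <- burstTable(detectBursts(clean, "source"))$peak_time
    # background far below the burst peak rate
    bg <- list(electrode = sample(srcIds, 15, replace = TRUE),
               time = runif(15, 0.9, 1.25))
    noisy <- makeSpikes(c(b$electrode, bg$electrode), c(b$time, bg$time),
                        duration = 3)
    p1 <- burstTable(detectBursts(noisy, "source"))$peak_time[1]
    abs(p1 - p0) * 1000
  }, numeric(1))
  expect_lt(stats::median(deltas), 5)
})

test_that("detected durations track the generator's 25 DIV regime", {
  rel <- vapply(1:3, function(s) {
    cfg <- simConfig(seed = s, duration = 300)
    sim <- simulateSpontaneous(cfg)
    stats <- burstDurationStats(detectBursts(sim$spikes, "source"))
    tr <- sim$truth@sourceBursts
    genMean <- mean((tr$offset - tr$onset) * 1000)
    stats$mean_ms / genMean
  }, numeric(1))
  expect_true(all(abs(rel - 1) < 0.15))
})
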
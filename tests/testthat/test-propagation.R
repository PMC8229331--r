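# minimal burst tables with given peak times (narrow intervals so arbitrary
# peak sets stay disjoint)
peaksToBurstSet <- function(peaks, module) {
  peaks <- sort(peaks)
  tb <- data.frame(onset = peaks - 5e-4, offset = peaks + 5e-4,
                   peak_time = peaks, duration_ms = rep(1, length(peaks)),
                   n_spikes = rep(50L, length(peaks)),
                   n_active = rep(10L, length(peaks)),
                   edge = rep(FALSE, length(peaks)))
  new("BurstSet", module = module, table = tb)
}

test_that("burst pairing matches nearest peaks within the window", {
  src <- peaksToBurstSet(10.000, "source")
  tgt <- peaksToBurstSet(10.050, "target")
  p <- pairBursts(src, tgt, window = 200)
  expect_equal(nrow(p), 1L)
  expect_equal(p$delay_ms, 50)

  expect_equal(nrow(pairBursts(src, peaksToBurstSet(numeric(0), "target"))), 0L)
  # outside the window: no pair
  expect_equal(nrow(pairBursts(src, peaksToBurstSet(10.5, "target"), 200)), 0L)
})

test_that("greedy pairing tracks the exhaustive optimal matching", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    ns <- sample(1:6, 1); nt <- sample(1:6, 1)
    sp <- sort(runif(ns, 0, 3)); tp <- sort(runif(nt, 0, 3))
    g <- pairBursts(data.frame(peak_time = sp), data.frame(peak_time = tp),
                    window = 200)
    opt <- bruteBestMatching(sp, tp, window = 200)
    gCost <- sum(abs(g$delay_ms))
    (nrow(g) == opt$n) && (opt$n == 0L || abs(gCost - opt$cost) < 1e-9)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("direction classification follows the peak-delay sign", {
  p <- data.frame(source_idx = 1:3, target_idx = 1:3,
                  source_peak = c(1, 2, 3), target_peak = c(1.03, 1.97, 3),
                  delay_ms = c(30, -30, 0))
  ev <- classifyDirection(p)
  expect_equal(ev$direction, c("forward", "backward"))
  expect_equal(attr(ev, "nZeroDelay"), 1L)
})

test_that("relabeling modules swaps forward and backward exactly", {
  for (s in 1:50) {
    set.seed(100 + s)
    src <- peaksToBurstSet(runif(sample(1:8, 1), 0, 10), "source")
    tgt <- peaksToBurstSet(runif(sample(1:8, 1), 0, 10) + 1e-5, "target")
    a <- propagationSummary(src, tgt, window = 200)
    b <- propagationSummary(
      new("BurstSet", module = "source", table = burstTable(tgt)),
      new("BurstSet", module = "target", table = burstTable(src)),
      window = 200)
    expect_equal(a@pForward, b@pBackward)
    expect_equal(a@pBackward, b@pForward)
    expect_equal(a@nForward, b@nBackward)
  }
})

test_that("propagation probabilities are the quoted burst-count ratios", {
  src <- peaksToBurstSet(seq(1, 100, length.out = 10), "source")
  tgt <- peaksToBurstSet(seq(1, 100, length.out = 10)[c(2, 5, 8)] + 0.05,
                         "target")
  s <- propagationSummary(src, tgt, window = 200)
  expect_equal(s@nForward, 3L)
  expect_equal(s@pForward, 0.3)
  expect_equal(s@pBackward, 0)   # no Target-to-Source events

  # zero denominators are NA, never 0
  s0 <- propagationSummary(src, peaksToBurstSet(numeric(0), "target"))
  expect_true(is.na(s0@pBackward))
  expect_equal(s0@pForward, 0)

  # events referencing absent bursts are an error
  badEv <- data.frame(source_idx = 99L, target_idx = 1L,
                      source_peak = 1, target_peak = 1.05,
                      delay_ms = 50, direction = "forward")
  expect_error(propagationSummary(src, tgt, events = badEv), "not in")
})

test_that("O/F relative difference is a plain ratio", {
  expect_equal(relativeDifference(1.56 * 7, 7), 1.56)
  expect_equal(relativeDifference(3, 3), 1)
  expect_equal(relativeDifference(0, 5), 0)
  expect_error(relativeDifference(1, 0), "zero")
})

test_that("pipeline estimate of pForward is consistent with the truth", {
  cfg <- simConfig(seed = 31, duration = 600, burstRate = 20, pForward = 0.25)
  sim <- simulateSpontaneous(cfg)
  res <- runSpontaneousPipeline(sim$spikes)
  expect_gte(res$summary@nSourceBursts, 150L)
  expect_lt(abs(res$summary@pForward - 0.25), 0.09)
  expect_equal(res$summary@pBackward, 0)
})

test_that("pForward error shrinks with the number of bursts", {
  # median absolute error over seeds decreases across increasing burst counts
  errs <- sapply(1:10, function(s) {
    vapply(c(150, 600, 2400), function(dur) {
      cfg <- simConfig(seed = 1000 + s, duration = dur, burstRate = 20,
                       pForward = 0.25, backgroundRate = 0.2)
      sim <- simulateSpontaneous(cfg)
      res <- runSpontaneousPipeline(sim$spikes)
      abs(res$summary@pForward - 0.25)
    }, numeric(1))
  })
  med <- apply(errs, 1, stats::median)
  expect_true(med[3] <= med[1])
})
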
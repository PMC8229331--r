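test_that("chip-specific analysis windows give 95 and 50 bins", {
  expect_equal(defaultWindow("fish"), c(10, 200))
  expect_equal(defaultWindow("octopus"), c(10, 110))
  st <- makeSpikes(integer(0), numeric(0), duration = 60)
  log <- makeTestProtocol(10, seed = 1)
  expect_equal(ncol(psthCounts(computePSTH(st, log, c(10, 200)))), 95L)
  expect_equal(ncol(psthCounts(computePSTH(st, log, c(10, 110)))), 50L)
  expect_error(defaultWindow("squid"))
})

test_that("PSTH counts and normalization follow the definition", {
  log <- stimulusLog(c(1, 3, 5), protocol = "test1", isiRange = c(1, 5))
  # no spikes: all-zero matrix
  st0 <- makeSpikes(integer(0), numeric(0), duration = 10)
  expect_true(all(psthCounts(computePSTH(st0, log)) == 0))

  # one spike 15 ms after each of 3 stimuli on one electrode:
  # the [14, 16) ms bin reads 1.0, everything else 0
  st <- makeSpikes(rep(5L, 3), c(1, 3, 5) + 0.015, duration = 10)
  m <- computePSTH(st, log)
  cnt <- psthCounts(m)
  binIdx <- (14 - 10) / 2 + 1
  expect_equal(unname(cnt["5", binIdx]), 1.0)
  expect_equal(sum(cnt), 1.0)
  expect_equal(nStimuli(m), 3L)
})

test_that("PSTH equals brute-force per-bin counts on random instances", {
  for (s in 1:20) {
    set.seed(s)
    nStim <- sample(3:8, 1)
    times <- 1 + cumsum(runif(nStim, 1, 5))
    log <- stimulusLog(times, protocol = "test1", isiRange = c(1, 5))
    st <- randomSpikeTable(300, duration = max(times) + 1)
    win <- if (s %% 2) c(10, 200) else c(10, 110)
    m <- computePSTH(st, log, win)
    expect_identical(psthRawCounts(m), brutePSTH(st, log, win))
    expect_equal(psthCounts(m) * nStimuli(m), psthRawCounts(m) + 0 * psthCounts(m))
  }
})

test_that("overlapping analysis windows are rejected with the stimulus pair", {
  st <- makeSpikes(1L, 0.5, duration = 10)
  expect_error(computePSTH(st, stimulusLog(c(1, 1.15), isiRange = c(0.1, 5)),
                           c(10, 200)),
               "stimuli 1 and 2")
})

test_that("mean PSTH sums bins per electrode and averages the module", {
  log <- stimulusLog(c(1, 3), protocol = "test1", isiRange = c(1, 5))
  st0 <- makeSpikes(integer(0), numeric(0), duration = 10)
  m0 <- computePSTH(st0, log)
  expect_true(all(meanPSTH(m0)$perElectrode == 0))

  # one electrode, 11 in-window spikes over 2 stimuli: mean PSTH 5.5
  times <- c(1 + seq(0.012, 0.19, length.out = 6),
             3 + seq(0.012, 0.19, length.out = 5))
  st <- makeSpikes(rep(7L, 11), times, duration = 10)
  mp <- meanPSTH(computePSTH(st, log), electrodes = 7L)
  expect_equal(mp$moduleMean, 5.5)
  expect_equal(unname(mp$perElectrode["7"]), 5.5)

  # module mean equals total in-window spikes / nStimuli on random tables
  for (s in 1:5) {
    set.seed(s)
    st <- randomSpikeTable(400, duration = 12)
    log <- stimulusLog(c(2, 5, 8), protocol = "test1", isiRange = c(1, 5))
    m <- computePSTH(st, log)
    all59 <- as.integer(rownames(psthCounts(m)))
    total <- sum(brutePSTH(st, log, c(10, 200)))
    expect_equal(sum(meanPSTH(m, all59)$perElectrode), total / 3)
  }
  expect_error(meanPSTH(computePSTH(st, log), integer(0)), "non-empty")
})

test_that("rank-sum test matches exhaustive enumeration and conventions", {
  # identical samples: no evidence, p = 1
  expect_equal(rankSumTest(c(1, 2, 3), c(1, 2, 3))$pValue, 1)

  # complete separation of 3 vs 3: U = 0, exact two-sided p = 0.1
  rs <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$U, 0)
  expect_equal(rs$method, "exact")
  expect_equal(rs$pValue, 0.1)
  expect_equal(rs$pValue, enumRankSumP(c(1, 2, 3), c(4, 5, 6)))

  # exact p equals label-permutation enumeration for all partitions <= 10
  set.seed(7)
  for (nx in 1:9) for (ny in 1:(10 - nx)) {
    pool <- sample(seq(0.01, 1, by = 0.01), nx + ny)
    x <- pool[seq_len(nx)]; y <- pool[-seq_len(nx)]
    rs <- rankSumTest(x, y)
    expect_equal(rs$method, "exact")
    expect_equal(rs$pValue, enumRankSumP(x, y), tolerance = 1e-12)
  }

  # normal approximation with continuity correction tracks the exact law
  set.seed(8)
  diffs <- vapply(1:30, function(i) {
    x <- rnorm(20); y <- rnorm(20, 0.3)
    rs <- rankSumTest(x, y)   # n = 40: approximate path
    pExact <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    c(rs$method == "approximate", abs(rs$pValue - pExact))
  }, numeric(2))
  expect_true(all(diffs[1, ] == 1))
  expect_lt(max(diffs[2, ]), 0.02)
})

test_that("plasticity classification follows significance and median shift", {
  el <- as.character(1:17)
  pre <- stats::setNames(rnorm(17, 0, 0.1), el)

  # identical samples: none, with no reported magnitude
  r0 <- classifyPlasticity(pre, pre)
  expect_equal(r0@label, "none")
  expect_true(is.na(r0@avgMagnitude))

  # uniform +10 shift over 17 electrodes: potentiation at p < 0.001
  post <- pre + 10
  r1 <- classifyPlasticity(pre, post)
  expect_equal(r1@label, "potentiation")
  expect_lt(r1@pValue, 0.001)
  expect_equal(r1@avgMagnitude, mean(abs(post)))

  # negating the POST sample flips the label at identical p
  r2 <- classifyPlasticity(pre, -post)
  expect_equal(r2@label, "depression")
  expect_equal(r2@pValue, r1@pValue)

  expect_error(classifyPlasticity(pre, unname(post)), "same electrodes")
})

test_that("tetanus changes are larger in the Target than the Source module", {
  labsT <- character(0)
  for (s in 1:3) {
    cfg <- simConfig(seed = 40 + s, tetanusEffect = 1.5)
    ex <- simulatePlasticityExperiment(cfg)
    rT <- runPlasticityPipeline(ex$test1, ex$test2, ex$test3, module = "target",
                                includeChannels = FALSE)
    rS <- runPlasticityPipeline(ex$test1, ex$test2, ex$test3, module = "source",
                                includeChannels = FALSE)
    expect_lt(mean(abs(rS$result@postDiffs)), mean(abs(rT$result@postDiffs)))
    labsT <- c(labsT, rT$result@label)
  }
  expect_true(all(labsT == "potentiation"))
})
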
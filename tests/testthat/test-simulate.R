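test_that("pattern config validates its parameters", {
  expect_error(patternConfig(10, 2, 3, lambdaIn = 0.01, lambdaOut = 0.02),
               "lambdaIn >= lambdaOut")
  expect_error(patternConfig(10, 2, 3, TEpoch = 20, TPulse = 30),
               "TPulse <= TEpoch")
  expect_error(patternConfig(10, 2, 3, mode = "bimodal", TEpoch = 50,
                             TPulse = 30), "bimodal")
  expect_s3_class(patternConfig(10, 2, 3), "PatternConfig")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- patternConfig(N = 12, nPatterns = 2, epochsPerPattern = 3,
                       noiseEpochs = 2, seed = 99)
  a <- generatePatterns(cfg)
  b <- generatePatterns(cfg)
  expect_identical(a@trains, b@trains)
  expect_identical(epochLabels(a), epochLabels(b))
  cfg2 <- patternConfig(N = 12, nPatterns = 2, epochsPerPattern = 3,
                        noiseEpochs = 2, seed = 100)
  expect_false(identical(generatePatterns(cfg2)@trains, a@trains))
})

test_that("per-neuron spike counts match the intensity integral", {
  # reference conditions: expected count 0.02*270 + 0.2*30 = 11.4
  cfg <- patternConfig(N = 20, nPatterns = 1, epochsPerPattern = 120,
                       noiseEpochs = 120, seed = 5)
  es <- generatePatterns(cfg)
  expected <- 0.02 * 270 + 0.2 * 30
  pat <- epochLabels(es)$pattern
  for (grp in c("noise", "P1")) {
    counts <- unlist(lapply(which(pat == grp), function(m)
      lengths(spikeTrains(es, m))))
    se <- sd(counts) / sqrt(length(counts))
    expect_lt(abs(mean(counts) - expected), 3 * se)
  }
})

test_that("degenerate pulse (lambdaIn == lambdaOut) is homogeneous", {
  cfg <- patternConfig(N = 4, nPatterns = 1, epochsPerPattern = 500,
                       noiseEpochs = 0, lambdaIn = 0.05, lambdaOut = 0.05,
                       seed = 6)
  es <- generatePatterns(cfg)
  counts <- unlist(lapply(seq_len(nEpochs(es)), function(m)
    lengths(spikeTrains(es, m))))
  expected <- 0.05 * 300
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("pattern identity lives in pulse placement, not rate totals", {
  cfg <- patternConfig(N = 25, nPatterns = 3, epochsPerPattern = 40,
                       noiseEpochs = 40, seed = 7)
  es <- generatePatterns(cfg)
  pat <- epochLabels(es)$pattern
  means <- tapply(seq_len(nEpochs(es)), pat, function(idx)
    mean(unlist(lapply(idx, function(m) lengths(spikeTrains(es, m))))))
  counts1 <- unlist(lapply(which(pat == "P1"), function(m)
    lengths(spikeTrains(es, m))))
  se <- sd(counts1) / sqrt(length(counts1))
  expect_lt(max(means) - min(means), 3 * se * sqrt(2))
})

test_that("bimodal and deactivation modes respect their intensity budgets", {
  for (mode in c("bimodal", "deactivation")) {
    cfg <- patternConfig(N = 15, nPatterns = 2, epochsPerPattern = 60,
                         noiseEpochs = 0, mode = mode, seed = 8,
                         lambdaIn = if (mode == "bimodal") 0.35 else 0.3,
                         lambdaOut = if (mode == "bimodal") 0.05 else 0.02,
                         TPulse = 20, TDeactivation = 150)
    es <- generatePatterns(cfg)
    expected <- spikeship:::.expectedCount(cfg)
    counts <- unlist(lapply(seq_len(nEpochs(es)), function(m)
      lengths(spikeTrains(es, m))))
    se <- sd(counts) / sqrt(length(counts))
    expect_lt(abs(mean(counts) - expected), 3 * se)
  }
})

test_that("global jitter shifts whole epochs and records offsets", {
  cfg <- patternConfig(N = 8, nPatterns = 1, epochsPerPattern = 2,
                       noiseEpochs = 0, seed = 9)
  es <- generatePatterns(cfg)
  # offsets all zero: identity
  same <- applyGlobalJitter(es, offsets = c(0, 0))
  expect_identical(same@trains, es@trains)
  # duplicate an epoch then shift the copy by +17
  ep <- spikeTrains(es, 1)
  es2 <- EpochedSpikes(list(ep, ep), neuronIds = neuronIds(es))
  sh <- applyGlobalJitter(es2, offsets = c(0, 17))
  d <- spikeShipPair(sh, 1, 2)
  expect_equal(d@dissimilarity, 0, tolerance = 1e-9)
  expect_equal(globalShift(d), 17, tolerance = 1e-9)
  expect_equal(epochLabels(sh)$offset, c(0, 17))
})

test_that("rate scaling preserves the motif and scales counts", {
  cfg <- patternConfig(N = 20, nPatterns = 2, epochsPerPattern = 50,
                       noiseEpochs = 0, seed = 10)
  es <- generatePatterns(cfg)
  scaled <- applyRateScaling(es, rep(3.5, nEpochs(es)), seed = 11)
  cs <- unlist(lapply(seq_len(nEpochs(scaled)), function(m)
    lengths(spikeTrains(scaled, m))))
  se <- sd(cs) / sqrt(length(cs))
  expect_lt(abs(mean(cs) - 3.5 * spikeship:::.expectedCount(cfg)), 3 * se)
  expect_error(applyRateScaling(es, rep(-1, nEpochs(es))), "positive")
  # local (per-neuron block) scaling: blocks move in opposite directions
  S <- matrix(1, nEpochs(es), nNeurons(es))
  S[, 1:10] <- 0.5; S[, 11:20] <- 2
  loc <- applyRateScaling(es, S, seed = 12)
  cntLow <- mean(unlist(lapply(seq_len(nEpochs(loc)), function(m)
    lengths(spikeTrains(loc, m))[1:10])))
  cntHigh <- mean(unlist(lapply(seq_len(nEpochs(loc)), function(m)
    lengths(spikeTrains(loc, m))[11:20])))
  expect_gt(cntHigh, 2.5 * cntLow)
})
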
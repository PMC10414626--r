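test_that("emdFlows matches the stated transport plans", {
  fl <- emdFlows(c(10, 15), 25)
  expect_equal(sort(fl$shift), c(10, 15))
  expect_equal(fl$mass, c(0.5, 0.5))
  expect_equal(sum(fl$mass), 1)

  fl <- emdFlows(c(5, 9, 13), c(5, 9, 13))
  expect_true(all(fl$shift == 0))
  expect_equal(sum(fl$mass), 1)

  fl <- emdFlows(c(0, 10), c(5, 20))
  expect_equal(fl$shift, c(5, 10))
  expect_equal(fl$mass, c(0.5, 0.5))

  expect_error(emdFlows(numeric(0), 1), "at least one spike")
  expect_error(emdFlows(1, numeric(0)), "at least one spike")
})

test_that("streaming flows equal the explicit-LCM brute force", {
  set.seed(11)
  for (rep in 1:500) {
    a <- sort(runif(sample(1:6, 1), 0, 100))
    b <- sort(runif(sample(1:6, 1), 0, 100))
    fl <- emdFlows(a, b)
    expect_lte(nrow(fl), length(a) + length(b) - 1)
    expect_equal(sum(fl$mass), 1, tolerance = 1e-12)
    expect_equal(sum(fl$mass * abs(fl$shift)), emdCostLcmOracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("weightedMedian reproduces the worked examples and ties", {
  expect_identical(weightedMedian(c(15, 30, 35, 45, 50, 60)), 40)
  expect_identical(
    weightedMedian(c(15, 10, 30, 30, 25, 30, 25, 25),
                   c(1/2, 1/2, 1/6, 1/6, 1/6, 1/6, 1/6, 1/6)), 20)
  expect_identical(weightedMedian(7, 3), 7)
  expect_error(weightedMedian(numeric(0)), "empty")
  expect_error(weightedMedian(c(1, 2), c(1, -1)), "positive")
})

test_that("weighted median minimises the L1 objective (grid oracle)", {
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(1:40, 1)
    v <- round(runif(n, -50, 50), 1)   # rounding forces frequent ties
    w <- sample(1:5, n, replace = TRUE) / 3
    g <- weightedMedian(v, w)
    expect_lte(wmObjective(g, v, w), wmGridMin(v, w) + 1e-9)
  }
})

test_that("sort-based and selection-based weighted medians agree exactly", {
  set.seed(8)
  for (rep in 1:200) {
    n <- sample(1:60, 1)
    v <- sample(seq(-20, 20, by = 0.5), n, replace = TRUE)
    w <- sample(c(1/6, 1/3, 1/2, 1, 2), n, replace = TRUE)
    expect_identical(weightedMedian(v, w, method = "sort"),
                     weightedMedian(v, w, method = "select"))
  }
})

test_that("single-spike pair decomposition matches the worked example", {
  k <- as.list(rep(10, 6))
  m <- as.list(c(25, 40, 45, 55, 60, 70))
  d <- spikeShipPair(k, m)
  expect_equal(sort(d@shifts), c(15, 30, 35, 45, 50, 60))
  expect_identical(globalShift(d), 40)
  expect_equal(sort(d@shifts - globalShift(d)), c(-25, -10, -5, 5, 10, 20))
  expect_equal(d@dissimilarity, 75 / 6)
  expect_equal(length(activeSet(d)), 6)
})

test_that("identical and translated epochs give F = 0 with shift recovery", {
  ep <- randEpoch(10, rate = 0.05, T = 100)
  ep <- lapply(ep, function(tr) if (length(tr)) tr else runif(1, 0, 100))
  d0 <- spikeShipPair(ep, ep)
  expect_identical(d0@dissimilarity, 0)
  expect_identical(globalShift(d0), 0)
  d1 <- spikeShipPair(ep, lapply(ep, function(tr) tr + 17.5))
  expect_equal(d1@dissimilarity, 0, tolerance = 1e-9)
  expect_equal(globalShift(d1), 17.5, tolerance = 1e-9)
})

test_that("degenerate pairs are flagged, not raised", {
  d <- spikeShipPair(list(numeric(0), 1), list(2, numeric(0)))
  expect_true(isDegenerate(d))
  expect_true(is.nan(d@dissimilarity))
  expect_true(is.nan(globalShift(d)))
})

test_that("active set keeps exactly the neurons spiking in both epochs", {
  k <- list(c(1, 2), numeric(0), 5, 7)
  m <- list(3, 4, numeric(0), 8)
  d <- spikeShipPair(k, m)
  expect_identical(activeSet(d), c(1L, 4L))
  expect_equal(sum(d@masses[d@neuron == 1]), 1)
  expect_equal(sum(d@masses[d@neuron == 4]), 1)
})

test_that("non-negativity, symmetry, translation and duplication hold", {
  set.seed(21)
  for (rep in 1:200) {
    k <- randEpoch(8, rate = 0.04, T = 150)
    m <- randEpoch(8, rate = 0.04, T = 150)
    dkm <- spikeShipPair(k, m)
    if (isDegenerate(dkm)) next
    dmk <- spikeShipPair(m, k)
    expect_gte(dkm@dissimilarity, 0)
    expect_equal(dkm@dissimilarity, dmk@dissimilarity, tolerance = 1e-12)
    # translation invariance with exact shift recovery
    delta <- runif(1, -40, 40)
    dtr <- spikeShipPair(k, lapply(m, function(tr) tr + delta))
    expect_equal(dtr@dissimilarity, dkm@dissimilarity, tolerance = 1e-9)
    expect_equal(globalShift(dtr), globalShift(dkm) + delta,
                 tolerance = 1e-9)
    # duplicating every spike r times changes nothing (rate invariance)
    r <- sample(c(2, 3, 5), 1)
    dup <- lapply(m, function(tr) rep(tr, each = r))
    ddup <- spikeShipPair(k, dup)
    expect_equal(ddup@dissimilarity, dkm@dissimilarity, tolerance = 1e-12)
    expect_equal(globalShift(ddup), globalShift(dkm), tolerance = 1e-12)
  }
})

test_that("single-spike epochs reduce to the median closed form", {
  set.seed(31)
  for (rep in 1:50) {
    N <- sample(3:12, 1)
    tk <- runif(N, 0, 100)
    tm <- runif(N, 0, 100)
    d <- spikeShipPair(as.list(tk), as.list(tm))
    cc <- tm - tk
    expect_equal(d@dissimilarity, mean(abs(cc - median(cc))),
                 tolerance = 1e-9)
  }
})

test_that("spikeShip fills symmetric F and antisymmetric G matrices", {
  set.seed(41)
  base <- randEpoch(12, rate = 0.05, T = 120)
  base <- lapply(base, function(tr) if (length(tr)) tr else runif(1, 0, 120))
  trains <- list(base,
                 lapply(base, function(tr) tr + 9),   # pure translation
                 randEpoch(12, rate = 0.05, T = 120),
                 randEpoch(12, rate = 0.05, T = 120))
  es <- EpochedSpikes(trains)
  res <- spikeShip(es)
  Fm <- fMatrix(res); Gm <- gMatrix(res)
  expect_identical(diag(Fm), setNames(rep(0, 4), epochIds(res)))
  expect_identical(Fm, t(Fm))
  expect_equal(Gm, -t(Gm), tolerance = 1e-9)
  expect_equal(Fm[1, 2], 0, tolerance = 1e-9)   # translation
  expect_equal(Gm[1, 2], 9, tolerance = 1e-9)
  expect_true(all(Fm[upper.tri(Fm)][-1] > 0))
  expect_error(spikeShip(es[, 1]), ">=2 epochs")
})

test_that("epochs with no common active neuron yield NaN matrix entries", {
  es <- EpochedSpikes(list(list(c(1, 2), numeric(0)),
                           list(numeric(0), c(3, 4)),
                           list(c(5), c(6))))
  res <- suppressMessages(spikeShip(es))
  expect_true(is.nan(fMatrix(res)[1, 2]))
  expect_true(is.nan(gMatrix(res)[2, 1]))
  expect_false(anyNA(fMatrix(res)[1, 3]))
  expect_equal(nrow(res@degeneratePairs), 1)
})

test_that("flowTable reports a mass-conserving long-format plan", {
  d <- spikeShipPair(list(c(1, 5), c(2, 3, 4)), list(c(2, 6), c(7)))
  ft <- flowTable(d)
  expect_named(ft, c("epoch_k", "epoch_m", "neuron_id", "shift", "mass"))
  agg <- tapply(ft$mass, ft$neuron_id, sum)
  expect_true(all(abs(agg - 1) < 1e-12))
})

test_that("pair cost grows sub-quadratically in N (logged, not gating)", {
  Ns <- c(100, 1000, 10000)
  times <- vapply(Ns, function(N) {
    set.seed(N)
    k <- lapply(seq_len(N), function(i) sort(runif(5, 0, 100)))
    m <- lapply(seq_len(N), function(i) sort(runif(5, 0, 100)))
    t0 <- proc.time()[["elapsed"]]
    for (r in 1:5) spikeShipPair(k, m, keepFlows = FALSE)
    proc.time()[["elapsed"]] - t0
  }, numeric(1))
  slope <- coef(lm(log(pmax(times, 1e-4)) ~ log(Ns)))[2]
  cat(sprintf("\n[complexity] N=%s times=%s slope=%.2f\n",
              paste(Ns, collapse = ","),
              paste(signif(times, 3), collapse = ","), slope))
  expect_true(is.finite(slope))
})
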
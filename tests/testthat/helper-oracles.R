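# Independent oracles and random-data helpers shared across tests.

# Total transport cost by explicit replication of each spike to the least
# common multiple of the two counts followed by sorted matching.  This is
# the brute-force definition that the streaming implementation must equal.
emdCostLcmOracle <- function(a, b) {
  a <- sort(a); b <- sort(b)
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  l <- length(a) * length(b) / gcd(length(a), length(b))
  ra <- rep(a, each = l / length(a))
  rb <- rep(b, each = l / length(b))
  sum(abs(rb - ra)) / l
}

# Weighted L1 objective minimised by the weighted median.
wmObjective <- function(g, v, w) sum(w * abs(v - g))

# Minimum of the objective over a dense grid spanning the data (the input
# values themselves are included: the minimiser is always at an input value
# or between two of them, where the objective is linear).
wmGridMin <- function(v, w, nGrid = 2001) {
  grid <- unique(c(seq(min(v), max(v), length.out = nGrid), v))
  min(vapply(grid, wmObjective, numeric(1), v = v, w = w))
}

# Random homogeneous-Poisson spike train on [0, T).
randTrain <- function(rate = 0.05, T = 200, minSpikes = 0) {
  repeat {
    n <- rpois(1, rate * T)
    if (n >= minSpikes) return(sort(runif(n, 0, T)))
  }
}

# Random epoch: list of N trains (possibly empty).
randEpoch <- function(N, rate = 0.05, T = 200) {
  lapply(seq_len(N), function(i) randTrain(rate, T))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
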
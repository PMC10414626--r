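---
title: "SpikeShip: methods, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpikeShip: methods, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeship)
```

## The model

SpikeShip measures the dissimilarity between two multi-neuron spiking
patterns in terms of their relative (inter-neuronal) spike timing.  The
data are epoched: `N` neurons by `M` epochs, each cell a sorted vector of
spike times in a consistent unit (the package is agnostic between seconds
and samples; everything downstream inherits that unit).  Spike times are
continuous reals and are never binned.

Each neuron's train in an epoch is normalised to unit mass: with `n`
spikes, each spike carries mass `1/n`.  For an epoch pair `(k, m)` the
computation has two steps.

1. **Per-neuron transport.**  For every neuron active in both epochs
   (the active set `A_km`; neurons silent in either epoch are excluded),
   the 1-D optimal transport between the two unit-mass trains is the
   monotone coupling of cumulative mass.  We stream it with two pointers,
   pairing mass increments of `1/n_k` against `1/n_m`; this is arithmetic
   on exact integer units of `1/(n_k n_m)` and is equivalent to replicating
   each spike to the least common multiple of the counts and matching in
   sorted order, without materialising replicas.  The result is at most
   `n_k + n_m - 1` flow segments `(c, w)`: a signed shift (second epoch
   minus first) and a positive mass; masses sum to 1 per neuron.
   Consecutive segments within a neuron that share a shift are merged,
   which changes nothing downstream and shrinks the pooled median input.

2. **Decomposition.**  All segments are pooled across neurons and the
   global shift `g_min` is their weighted median — the rigid temporal
   translation that minimises the total residual transport cost.  The
   neuron-specific flows are the residuals `f = c - g_min`, and

   `F_km = mean over A_km of sum_u w_u |f_u|`.

`F` is symmetric, non-negative, zero exactly for pure translations, and
invariant to firing-rate scaling and spike duplication (unit-mass
normalisation).  `g_min` is reported in the companion matrix `G` as a
pattern-latency estimate; under the tie convention below `G` is
antisymmetric.  The cost of a pair is linear in the total spike count, and
a full matrix is `O(M^2 N n)`; the kernels are compiled C++.

## Numerical conventions

* **Weighted-median ties.**  When the cumulative weight hits exactly half
  the total at an input value, the minimiser is an interval; the package
  returns its **midpoint**.  `F` is tie-invariant (the objective is flat on
  the interval) but reported global shifts are not, so the convention is
  fixed.  Exact hits are detected with a relative tolerance of `1e-9`,
  which absorbs the rounding of sums of masses like `1/6`.
* **Two median algorithms.**  A sort-based cumulative scan (default) and an
  expected-linear-time quickselect on cumulative weights, which keeps the
  whole pipeline `O(N n)`; the test suite checks they agree exactly,
  including on tied boundaries.
* **Sign convention.**  Flows are `t_m - t_k`, so `G[k, m] > 0` means epoch
  `m`'s pattern occurs later than epoch `k`'s.
* **Degenerate pairs.**  If no neuron is active in both epochs, the pair is
  flagged and carries `NaN` in both matrices rather than raising, so full
  matrices on sparse data remain computable; degenerate pairs are listed in
  the result and counted in the log.
* **Equality tolerances.**  Internal equality assertions use `1e-9`
  absolute on the time-unit scale.

## Comparison measures

* **Victor–Purpura** (`victorPurpura`, `vpMatrix`): the standard dynamic
  program with insert/delete cost 1 and shift cost `q` per unit time
  (capped at 2).  At `q = 0` it is the absolute spike-count difference; for
  large `q` it converges to the summed counts.  For equal-count trains,
  `(T/n) VP(q = 1/T)` equals the absolute-time earth-mover distance
  `emdAbsolute` — the suite verifies this identity on random pairs.  The
  population version averages per-neuron distances; the label-exchange
  extension (hyperparameter `k`) is deliberately not implemented.
* **Rate distance** (`rateDistanceMatrix`): per-neuron firing rates
  (count / `T`) are z-scored **across epochs with the population
  (divide-by-M) standard deviation** — forced by the worked example the
  implementation reproduces — and compared by Euclidean distance.
  Zero-variance neurons get z-score 0, removing constant neurons as the
  normalisation intends.
* **Discriminability index** (`discriminabilityIndex`):
  `d = (mu_between - mu_within) / sqrt(s2_between + s2_within)` per label,
  off-diagonal entries only.  The source prose for this index is ambiguous
  between this d′-style denominator and the raw sum of variances; the
  square-root reading is used because it makes `d` a separation in pooled
  standard-deviation units (the stated interpretation), and the sign and
  ordering of `d` are unaffected either way.  Variances are population
  variances so a label with a single within-pair is still defined; a zero
  denominator with positive numerator is reported as `Inf` and flagged.

## The synthetic-data generator

`generatePatterns` emulates the simulation protocols used to validate the
measure.  A pattern is a fixed spatiotemporal motif: each neuron receives a
pulse onset drawn uniformly on `[0, T_epoch - T_pulse]`, fixed per
(pattern, neuron) — onsets are independent across neurons, which reproduces
the intended "fixed motif, no common latency" structure.  Per epoch, spikes
are drawn from the piecewise-constant intensity (`lambdaIn` inside the
pulse, `lambdaOut` outside).  Defaults are the reference conditions:
`T_epoch = 300` samples, `T_pulse = 30`, `lambdaIn = 0.2`,
`lambdaOut = 0.02` spikes/sample (expected 11.4 spikes per neuron per
epoch).  Noise epochs are homogeneous Poisson with the **expected count
matched** to the patterned epochs (not conditioned on realised counts), so
pattern identity is encoded only in timing.  `bimodal` places two
non-overlapping pulses; `deactivation` silences a window of length
`TDeactivation` against a `lambdaIn` background.

`applyGlobalJitter` adds a recorded per-epoch offset to every spike
(emulating unknown pattern onsets); `applyRateScaling` **regenerates** the
affected trains from the scaled intensity — preserving each motif's pulse
placement — rather than thinning, so scaled data are again exact Poisson
draws; it accepts one factor per epoch (global rate states) or a full
epoch-by-neuron matrix (local, e.g. opposite scaling of two neuron blocks).
All generators are pure functions of (config, seed).

What the simulations do *not* emulate: refractoriness, burstiness,
correlated trial-to-trial variability, non-Poisson interval statistics, and
drifting motifs.  Passing the simulation-based tests therefore shows the
measure recovers planted relative-timing structure under Poisson
variability — not that any particular real dataset contains such structure.

## Windowing and window-length selection

`epochsFromWindows` slices continuous recordings with half-open windows
`[t, t + T_w)` (boundary spikes counted once; tiling is loss-free), times
re-expressed relative to window start, default hop `T_w / 2`.
`selectWindowLength` scores each candidate length by: epoching, SpikeShip
matrix, cluster labels, mean silhouette width.  The silhouette is computed
**directly on the dissimilarity matrix**, not on an embedding — the
original figure pipeline scored embeddings, but the matrix itself is the
object of interest and the direct score is deterministic.  Candidates with
fewer than two usable epochs or a single cluster are scored missing, never
zero; ties go to the shorter window.

## Clustering

`clusterEpochs` assigns labels from a precomputed dissimilarity matrix.
The default is a classic DBSCAN on the matrix (written in-package; only
HDBSCAN-class libraries were considered out of scope): patterned epochs
form dense clumps while matched-rate noise epochs are mutually distant and
fall out as density noise, which is exactly the generative structure.  Two
knobs:

* `eps` defaults to the widest gap in the sorted `minPts`-nearest-neighbour
  distances (the usual knee heuristic) — with a diffuse noise class the
  kNN curve has a pronounced jump between clustered and unclustered epochs.
* `minPts = 6`: a core point needs six neighbours (itself included) within
  `eps`.  The package takes the stance that a sequence must recur about six
  times before it counts as a discoverable cluster; smaller cores let
  chance proximities among homogeneous noise epochs surface as spurious
  few-member clusters, which a six-neighbour core suppresses.

`pam` and average-linkage `hclust` are available when the number of
clusters is known.  Cluster quality against ground truth is measured with
the adjusted Rand index (`mclust::adjustedRandIndex`); DBSCAN's noise label
is treated as one additional class, matching how the noise condition is
labelled in the simulations.

## Problem sizes in the shipped tests

The simulation-based tests run at desk scale, chosen to keep the full suite
under a minute of compute while leaving comfortable Monte-Carlo margins:
50 neurons; 6 patterns x 10 epochs with 60 matched-rate noise epochs for
the clustering scenario; 6 x 10 patterned epochs with offsets uniform on
`[0, 240]` samples for latency recovery; 2 patterns x 15 epochs across
three global rate states (x1, x2, x3.5) and a two-block local variant for
rate invariance; oracle suites use 100-500 random train pairs with up to
six spikes each.  The complexity smoke test fits a log-log slope over
`N = 100, 1000, 10000` and only logs it.

## Known limitations

* SpikeShip is a dissimilarity, not a proven metric: no triangle-inequality
  claim is made or tested (symmetry and identity are).
* Epochs with no commonly active neuron are incomparable (`NaN`), and very
  low firing rates shrink the active set: the value is rate-invariant, but
  which neurons it is computed over is not.
* The latency estimate `G` is convention-dependent on tied medians
  (midpoint rule) and is meaningful only up to the within-pattern timing
  spread.
* The CLI reads the whole spike table into memory; recordings far beyond
  10^7 spikes should be windowed upstream.
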
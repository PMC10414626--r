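#' Configuration of a synthetic spiking-pattern ensemble
#'
#' Parameters of the inhomogeneous-Poisson pattern generator.  Each pattern
#' is a fixed spatiotemporal motif: every neuron is assigned a pulse window
#' (pattern-fixed, uniform placement within the epoch) during which it fires
#' at \code{lambdaIn}, and fires at \code{lambdaOut} outside it.  Noise
#' epochs are homogeneous Poisson with the same expected spike count as the
#' patterned epochs.  The defaults are the reference simulation conditions:
#' 300-sample epochs, 30-sample pulses, 0.2 spikes/sample inside the pulse
#' and 0.02 outside.
#'
#' @param N number of neurons.
#' @param nPatterns number of distinct patterns.
#' @param epochsPerPattern epochs per pattern.
#' @param noiseEpochs number of homogeneous matched-rate noise epochs.
#' @param TEpoch epoch length (samples).
#' @param TPulse pulse length (samples); for \code{mode = "bimodal"} each of
#'   the two pulses has this length.
#' @param lambdaIn,lambdaOut firing rate inside / outside the pulse
#'   (spikes/sample); must satisfy \code{lambdaIn >= lambdaOut >= 0}.
#' @param TDeactivation length of the silenced window for
#'   \code{mode = "deactivation"} (background fires at \code{lambdaIn},
#'   the window at \code{lambdaOut}).
#' @param mode \code{"unimodal"} (one pulse), \code{"bimodal"} (two
#'   non-overlapping pulses) or \code{"deactivation"}.
#' @param seed integer seed; generators are pure functions of
#'   (config, seed).
#' @return validated config list of class \code{"PatternConfig"}.
#' @export
patternConfig <- function(N, nPatterns, epochsPerPattern, noiseEpochs = 0,
                          TEpoch = 300, TPulse = 30,
                          lambdaIn = 0.2, lambdaOut = 0.02,
                          TDeactivation = 150,
                          mode = c("unimodal", "bimodal", "deactivation"),
                          seed = 1L) {
  mode <- match.arg(mode)
  if (!(lambdaIn >= lambdaOut && lambdaOut >= 0))
    stop("patternConfig: need lambdaIn >= lambdaOut >= 0")
  if (TPulse > TEpoch || TPulse <= 0 || TEpoch <= 0)
    stop("patternConfig: need 0 < TPulse <= TEpoch")
  if (mode == "bimodal" && 2 * TPulse > TEpoch)
    stop("patternConfig: bimodal mode needs 2*TPulse <= TEpoch")
  if (mode == "deactivation" && TDeactivation > TEpoch)
    stop("patternConfig: need TDeactivation <= TEpoch")
  if (N < 1 || nPatterns < 0 || epochsPerPattern < 0 || noiseEpochs < 0)
    stop("patternConfig: counts must be non-negative (N >= 1)")
  structure(list(N = as.integer(N), nPatterns = as.integer(nPatterns),
                 epochsPerPattern = as.integer(epochsPerPattern),
                 noiseEpochs = as.integer(noiseEpochs),
                 TEpoch = TEpoch, TPulse = TPulse,
                 lambdaIn = lambdaIn, lambdaOut = lambdaOut,
                 TDeactivation = TDeactivation, mode = mode,
                 seed = as.integer(seed)),
            class = "PatternConfig")
}

# Piecewise-constant-rate Poisson spike train on [0, TEpoch).
# segs: matrix with columns (start, end, rate); segments are disjoint.
.simTrain <- function(segs) {
  times <- numeric(0)
  for (r in seq_len(nrow(segs))) {
    len <- segs[r, 2] - segs[r, 1]
    n <- rpois(1, segs[r, 3] * len)
    if (n > 0) times <- c(times, runif(n, segs[r, 1], segs[r, 2]))
  }
  sort(times)
}

# Rate segments for one neuron in one patterned epoch.
.patternSegments <- function(cfg, onsets, i) {
  T <- cfg$TEpoch; Tp <- cfg$TPulse
  if (cfg$mode == "unimodal") {
    o <- onsets[i, 1]
    rbind(c(0, o, cfg$lambdaOut), c(o, o + Tp, cfg$lambdaIn),
          c(o + Tp, T, cfg$lambdaOut))
  } else if (cfg$mode == "bimodal") {
    o1 <- onsets[i, 1]; o2 <- onsets[i, 2]
    rbind(c(0, o1, cfg$lambdaOut), c(o1, o1 + Tp, cfg$lambdaIn),
          c(o1 + Tp, o2, cfg$lambdaOut), c(o2, o2 + Tp, cfg$lambdaIn),
          c(o2 + Tp, T, cfg$lambdaOut))
  } else {  # deactivation: lambdaIn background, silenced window at lambdaOut
    o <- onsets[i, 1]; Td <- cfg$TDeactivation
    rbind(c(0, o, cfg$lambdaIn), c(o, o + Td, cfg$lambdaOut),
          c(o + Td, T, cfg$lambdaIn))
  }
}

# Expected spike count per neuron per patterned epoch (used to match noise).
.expectedCount <- function(cfg) {
  T <- cfg$TEpoch; Tp <- cfg$TPulse
  switch(cfg$mode,
    unimodal = cfg$lambdaOut * (T - Tp) + cfg$lambdaIn * Tp,
    bimodal = cfg$lambdaOut * (T - 2 * Tp) + cfg$lambdaIn * 2 * Tp,
    deactivation = cfg$lambdaIn * (T - cfg$TDeactivation) +
      cfg$lambdaOut * cfg$TDeactivation)
}

#' Generate an ensemble of synthetic spiking patterns
#'
#' Draws epochs from per-pattern inhomogeneous Poisson processes.  Pattern
#' identity lives only in the pulse placement (one pulse onset per neuron,
#' uniform on the admissible range, fixed for all epochs of the pattern) —
#' never in the total rate, since noise epochs are homogeneous Poisson with
#' the same expected spike count.  Noise epochs come first, then the
#' patterned epochs grouped by pattern, with ground-truth labels in
#' \code{epochLabels}.  Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{patternConfig}}.
#' @return \code{\linkS4class{EpochedSpikes}} with a \code{pattern} label
#'   column ("noise", "P1", "P2", ...) and the pulse placements kept in
#'   \code{metadata} for rate-scaling regeneration.
#' @examples
#' es <- generatePatterns(patternConfig(N = 30, nPatterns = 2,
#'   epochsPerPattern = 5, noiseEpochs = 5, seed = 7))
#' table(epochLabels(es)$pattern)
#' @export
generatePatterns <- function(cfg) {
  stopifnot(inherits(cfg, "PatternConfig"))
  set.seed(cfg$seed)
  T <- cfg$TEpoch; Tp <- cfg$TPulse
  # pattern-fixed pulse placements, independent per neuron
  onsets <- vector("list", cfg$nPatterns)
  for (p in seq_len(cfg$nPatterns)) {
    if (cfg$mode == "unimodal") {
      onsets[[p]] <- cbind(runif(cfg$N, 0, T - Tp))
    } else if (cfg$mode == "bimodal") {
      o1 <- runif(cfg$N, 0, T - 2 * Tp)
      o2 <- runif(cfg$N, o1 + Tp, T - Tp)
      onsets[[p]] <- cbind(o1, o2)
    } else {
      onsets[[p]] <- cbind(runif(cfg$N, 0, T - cfg$TDeactivation))
    }
  }
  lambdaNoise <- .expectedCount(cfg) / T
  trains <- list(); pattern <- character(0)
  for (e in seq_len(cfg$noiseEpochs)) {
    trains[[length(trains) + 1L]] <- lapply(seq_len(cfg$N), function(i)
      .simTrain(cbind(0, T, lambdaNoise)))
    pattern <- c(pattern, "noise")
  }
  for (p in seq_len(cfg$nPatterns)) for (e in seq_len(cfg$epochsPerPattern)) {
    trains[[length(trains) + 1L]] <- lapply(seq_len(cfg$N), function(i)
      .simTrain(.patternSegments(cfg, onsets[[p]], i)))
    pattern <- c(pattern, sprintf("P%d", p))
  }
  M <- length(trains)
  EpochedSpikes(trains,
    neuronIds = sprintf("n%0*d", nchar(cfg$N), seq_len(cfg$N)),
    epochIds = sprintf("e%0*d", max(2L, nchar(M)), seq_len(M)),
    labels = data.frame(pattern = pattern, stringsAsFactors = FALSE),
    timeUnit = "samples",
    metadata = list(config = cfg, onsets = onsets))
}

#' Apply a global temporal offset to each epoch
#'
#' Shifts every spike of each epoch by a per-epoch offset, emulating
#' patterns whose onset is not locked to the epoch start.  Offsets are drawn
#' uniformly on \code{[-maxOffset, maxOffset]} (or supplied directly) and
#' recorded in the \code{offset} label column so that recovery through the
#' global-shift matrix can be checked.  Spikes are shifted, never cropped;
#' windowing decides what falls outside an analysis span.
#'
#' @param x an \code{\linkS4class{EpochedSpikes}} object.
#' @param maxOffset non-negative half-range of the uniform offset draw.
#' @param offsets optional explicit numeric vector of per-epoch offsets
#'   (overrides \code{maxOffset}).
#' @param seed integer seed for the draw.
#' @return the shifted \code{EpochedSpikes} with an \code{offset} label
#'   column.
#' @export
applyGlobalJitter <- function(x, maxOffset = NULL, offsets = NULL,
                              seed = 1L) {
  stopifnot(is(x, "EpochedSpikes"))
  M <- nEpochs(x)
  if (is.null(offsets)) {
    if (is.null(maxOffset) || maxOffset < 0)
      stop("applyGlobalJitter: need a non-negative maxOffset or offsets")
    set.seed(seed)
    offsets <- runif(M, -maxOffset, maxOffset)
  }
  if (length(offsets) != M)
    stop("applyGlobalJitter: one offset per epoch required")
  trains <- lapply(seq_len(M), function(m)
    lapply(x@trains[[m]], function(tr) tr + offsets[m]))
  labels <- x@labels
  labels$offset <- offsets
  new("EpochedSpikes", trains = trains, neuronIds = x@neuronIds,
      epochIds = x@epochIds, labels = labels, timeUnit = x@timeUnit,
      metadata = x@metadata)
}

#' Rescale firing rates by regenerating from the scaled intensity
#'
#' Redraws every affected spike train from the original piecewise-constant
#' intensity multiplied by a scale factor, preserving each pattern's pulse
#' placement (the motif) while changing its rate state.  This emulates
#' global rate fluctuations (one scale per epoch) or local ones (a full
#' epochs-by-neurons scale matrix, e.g. opposite scaling of two neuron
#' blocks).  Regeneration — not thinning — so the result is again an exact
#' inhomogeneous Poisson draw.  Requires an object produced by
#' \code{\link{generatePatterns}} (the intensity lives in its metadata).
#'
#' @param x an \code{\linkS4class{EpochedSpikes}} from
#'   \code{\link{generatePatterns}}.
#' @param scale either a positive numeric vector of length M (global, one
#'   factor per epoch) or a positive M x N matrix (local, per epoch and
#'   neuron).
#' @param seed integer seed for the redraw.
#' @return rescaled \code{EpochedSpikes} with a \code{rate_scale} label
#'   column (the per-epoch scale, or its per-epoch mean in local mode).
#' @export
applyRateScaling <- function(x, scale, seed = 1L) {
  stopifnot(is(x, "EpochedSpikes"))
  cfg <- x@metadata$config; onsets <- x@metadata$onsets
  if (is.null(cfg) || is.null(onsets))
    stop("applyRateScaling: x must carry generator metadata ",
         "(use generatePatterns())")
  M <- nEpochs(x); N <- nNeurons(x)
  if (is.matrix(scale)) {
    if (!all(dim(scale) == c(M, N)))
      stop("applyRateScaling: scale matrix must be M x N")
    S <- scale
  } else {
    if (length(scale) != M)
      stop("applyRateScaling: need one scale per epoch")
    S <- matrix(scale, M, N)
  }
  if (any(S <= 0)) stop("applyRateScaling: scales must be positive")
  set.seed(seed)
  pat <- x@labels$pattern
  lambdaNoise <- .expectedCount(cfg) / cfg$TEpoch
  trains <- lapply(seq_len(M), function(m) {
    lapply(seq_len(N), function(i) {
      segs <- if (pat[m] == "noise") cbind(0, cfg$TEpoch, lambdaNoise)
              else .patternSegments(cfg, onsets[[as.integer(sub("P", "", pat[m]))]], i)
      segs[, 3] <- segs[, 3] * S[m, i]
      .simTrain(segs)
    })
  })
  labels <- x@labels
  labels$rate_scale <- rowMeans(S)
  new("EpochedSpikes", trains = trains, neuronIds = x@neuronIds,
      epochIds = x@epochIds, labels = labels, timeUnit = x@timeUnit,
      metadata = x@metadata)
}
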
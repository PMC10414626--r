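#' Optimal transport flows between two spike trains
#'
#' Computes the monotone (order-preserving) optimal-transport plan between
#' two spike trains treated as unit-mass 1-D distributions: each spike of
#' \code{a} carries mass \code{1/length(a)}, each spike of \code{b} mass
#' \code{1/length(b)}.  The plan is streamed by pairing cumulative masses of
#' the two sorted trains — equivalent to replicating each spike to the least
#' common multiple of the two counts and matching in sorted order, without
#' materializing the replicas — and has at most
#' \code{length(a) + length(b) - 1} segments.  Consecutive segments with an
#' identical shift are merged.
#'
#' @param a,b numeric spike-time vectors (sorted internally); both must be
#'   non-empty.
#' @return data.frame with columns \code{shift} (signed, \code{b} time minus
#'   matched \code{a} time) and \code{mass} (positive, summing to 1).
#' @examples
#' emdFlows(c(10, 15), 25)   # shifts +15 and +10, each with mass 1/2
#' @seealso \code{\link{emdAbsolute}}, \code{\link{spikeShipPair}}
#' @export
emdFlows <- function(a, b) {
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  if (length(a) == 0 || length(b) == 0)
    stop("emdFlows: both spike trains must contain at least one spike")
  res <- .cppEmdFlows(a, b)
  data.frame(shift = res$shift, mass = res$mass)
}

#' Absolute-time earth mover distance between two spike trains
#'
#' The plain 1-D earth mover distance between the two unit-mass trains,
#' i.e. the total mass-weighted absolute shift of \code{\link{emdFlows}}
#' with no global-shift subtraction.  Sensitive to absolute spike timing;
#' used e.g. to relate the Victor-Purpura distance at shift cost
#' \code{q = 1/T} to transport cost for equal-count trains.
#'
#' @inheritParams emdFlows
#' @return non-negative scalar.
#' @examples
#' emdAbsolute(c(10, 15), 25)  # (15 + 10)/2 = 12.5
#' @export
emdAbsolute <- function(a, b) {
  fl <- emdFlows(a, b)
  sum(fl$mass * abs(fl$shift))
}

#' Weighted median with midpoint tie convention
#'
#' Returns a minimizer \code{g} of \code{sum(w * abs(v - g))}.  When the
#' cumulative weight reaches exactly half the total weight at an input value
#' the minimizer is a whole interval; the midpoint of that interval is
#' returned.  The achieved objective value is the same for any point of the
#' interval, so downstream dissimilarities do not depend on the convention,
#' but reported global shifts do, hence it is fixed and documented here.
#'
#' @param values numeric vector.
#' @param weights positive weights, recycled scalar allowed; default equal.
#' @param method \code{"sort"} (cumulative-weight scan after sorting) or
#'   \code{"select"} (expected-linear-time quickselect on cumulative
#'   weights).  Both return identical results; the selection path keeps the
#'   whole pipeline linear in the number of spikes.
#' @return scalar weighted median.
#' @examples
#' weightedMedian(c(15, 30, 35, 45, 50, 60))            # 40 (interval midpoint)
#' weightedMedian(c(15, 10, 30, 30, 25, 30, 25, 25),
#'                c(3, 3, 1, 1, 1, 1, 1, 1) / 6)        # 20
#' @export
weightedMedian <- function(values, weights = NULL,
                           method = c("sort", "select")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (length(values) == 0) stop("weightedMedian: empty input")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) == 1) weights <- rep(weights, length(values))
  if (length(weights) != length(values))
    stop("weightedMedian: values and weights must have equal length")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weightedMedian: weights must be positive")
  .cppWeightedMedian(values, as.numeric(weights), method)
}

#' SpikeShip flow decomposition for one epoch pair
#'
#' Computes the optimal transport between the multi-neuron spiking patterns
#' of two epochs and decomposes it into a global rigid temporal translation
#' and neuron-specific flows.  Per active neuron (at least one spike in both
#' epochs) the order-preserving transport plan between the two unit-mass
#' trains is streamed; all per-segment shifts are pooled with their masses
#' and the global shift is their weighted median.  The dissimilarity is the
#' mean over active neurons of the mass-weighted absolute residual flows —
#' zero exactly when the two patterns are temporal translations of one
#' another, and invariant to firing-rate scaling because every neuron's
#' train is normalized to unit mass.
#'
#' Shift convention: flows are \code{t_m - t_k} (epoch \code{m} minus epoch
#' \code{k}), so a positive \code{globalShift} means epoch \code{m}'s
#' pattern occurs later.
#'
#' @param x an \code{\linkS4class{EpochedSpikes}} object, or a list of
#'   per-neuron spike-time vectors for epoch k (then \code{k} must be the
#'   corresponding list for epoch m).
#' @param k,m epoch identifiers or indices when \code{x} is
#'   \code{EpochedSpikes}; when \code{x} is a plain list, \code{k} is the
#'   second epoch's list and \code{m} is ignored.
#' @param keepFlows keep the per-segment transport plan in the result
#'   (needed for \code{\link{flowTable}}).
#' @return A \code{\linkS4class{FlowDecomposition}}.  When no neuron is
#'   active in both epochs the result is flagged degenerate with \code{NaN}
#'   dissimilarity and global shift (no error is raised, so full matrices on
#'   sparse data remain computable).
#' @examples
#' k <- as.list(rep(10, 6)); m <- as.list(c(25, 40, 45, 55, 60, 70))
#' d <- spikeShipPair(k, m)
#' globalShift(d)   # 40
#' d@dissimilarity  # 75/6
#' @export
spikeShipPair <- function(x, k, m = NULL, keepFlows = TRUE) {
  if (is(x, "EpochedSpikes")) {
    ik <- .resolveEpoch(x, k); im <- .resolveEpoch(x, m)
    trainsK <- x@trains[[ik]]; trainsM <- x@trains[[im]]
    ids <- x@epochIds[c(ik, im)]
    nids <- x@neuronIds
  } else {
    trainsK <- lapply(x, as.numeric)
    trainsM <- lapply(k, as.numeric)
    ids <- c("k", "m")
    nids <- sprintf("n%d", seq_along(trainsK))
  }
  res <- .cppSpikeShipPair(trainsK, trainsM, keepFlows)
  cost <- as.numeric(res$perNeuronCost)
  names(cost) <- nids[res$activeSet]
  new("FlowDecomposition",
      dissimilarity = as.numeric(res$F), globalShift = as.numeric(res$gMin),
      shifts = as.numeric(res$shift), masses = as.numeric(res$mass),
      neuron = as.integer(res$neuron), activeSet = as.integer(res$activeSet),
      perNeuronCost = cost, degenerate = as.logical(res$degenerate),
      epochPair = ids)
}

#' Pairwise SpikeShip dissimilarity matrix
#'
#' Runs \code{\link{spikeShipPair}} over all epoch pairs and assembles the
#' symmetric dissimilarity matrix together with the companion global-shift
#' matrix (\code{G[k, m]} = weighted-median flow of epoch m relative to
#' epoch k; antisymmetric under the midpoint tie convention).  Pairs with no
#' commonly active neuron get \code{NaN} in both matrices and are recorded.
#'
#' @param x an \code{\linkS4class{EpochedSpikes}} object with at least two
#'   epochs.
#' @return A \code{\linkS4class{DissimilarityResult}}.
#' @examples
#' es <- generatePatterns(patternConfig(N = 20, nPatterns = 2,
#'   epochsPerPattern = 3, noiseEpochs = 0, seed = 1))
#' res <- spikeShip(es)
#' fMatrix(res)[1:3, 1:3]
#' @export
spikeShip <- function(x) {
  stopifnot(is(x, "EpochedSpikes"))
  M <- nEpochs(x)
  if (M < 2) stop("spikeShip: need >=2 epochs")
  res <- .cppSpikeShipMatrix(x@trains)
  Fm <- res$F; Gm <- res$G
  dimnames(Fm) <- dimnames(Gm) <- list(x@epochIds, x@epochIds)
  deg <- cbind(k = as.integer(res$degenerateK),
               m = as.integer(res$degenerateM))
  if (length(res$degenerateK))
    message("spikeShip: ", nrow(deg), " degenerate epoch pair(s)")
  new("DissimilarityResult", FMatrix = Fm, GMatrix = Gm,
      epochIds = x@epochIds, degeneratePairs = deg)
}
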
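#' @useDynLib spikeship, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is setValidity show
#' @importFrom stats rpois runif median cor quantile rnorm cutree hclust as.dist
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

#' Epoched multi-neuron spike data
#'
#' Container for the spike times of \code{N} neurons across \code{M} epochs
#' (trials, stimulus presentations, or sliding windows).  Each cell of the
#' grid is one neuron's sorted spike-time vector in one epoch; empty trains
#' are legal and kept, so the grid is always complete.  Spike times are
#' continuous reals in a consistent unit (samples or seconds) and are never
#' binned.
#'
#' @slot trains list of length \code{M}; element \code{m} is a list of
#'   length \code{N} of sorted numeric spike-time vectors.
#' @slot neuronIds character vector of \code{N} unique neuron identifiers.
#' @slot epochIds character vector of \code{M} unique epoch identifiers.
#' @slot labels data.frame with one row per epoch (column \code{epoch_id}
#'   plus any annotation columns such as ground-truth pattern labels,
#'   applied offsets or rate states); may have zero columns.
#' @slot timeUnit free-text tag for the time unit (e.g. "samples").
#' @slot metadata list of generator provenance (epoch length, pulse
#'   placements, simulation config) used e.g. by \code{\link{applyRateScaling}}.
#'
#' @seealso \code{\link{EpochedSpikes}}, \code{\link{readSpikeTable}},
#'   \code{\link{generatePatterns}}
#' @export
setClass("EpochedSpikes",
  representation(trains = "list", neuronIds = "character",
                 epochIds = "character", labels = "data.frame",
                 timeUnit = "character", metadata = "list"))

setValidity("EpochedSpikes", function(object) {
  M <- length(object@epochIds)
  N <- length(object@neuronIds)
  if (length(object@trains) != M)
    return("number of epochs in 'trains' does not match 'epochIds'")
  if (anyDuplicated(object@epochIds)) return("epoch ids must be unique")
  if (anyDuplicated(object@neuronIds)) return("neuron ids must be unique")
  for (m in seq_len(M)) {
    ep <- object@trains[[m]]
    if (length(ep) != N)
      return(sprintf("epoch %d does not cover the neuron index space", m))
    for (tr in ep) {
      if (!is.numeric(tr)) return("spike trains must be numeric vectors")
      if (is.unsorted(tr)) return("spike times must be non-decreasing")
    }
  }
  if (nrow(object@labels) > 0 && nrow(object@labels) != M)
    return("'labels' must have one row per epoch")
  TRUE
})

#' Construct an EpochedSpikes object
#'
#' @param trains list of length \code{M} of lists of length \code{N} of
#'   numeric spike-time vectors; times are sorted on construction.
#' @param neuronIds,epochIds identifiers; defaults are generated.
#' @param labels optional per-epoch data.frame (must contain or will be
#'   given an \code{epoch_id} column).
#' @param timeUnit free-text unit tag.
#' @param metadata provenance list.
#' @return An \code{\linkS4class{EpochedSpikes}} object.
#' @examples
#' es <- EpochedSpikes(list(list(c(1, 2), 3), list(numeric(0), c(2.5, 4))))
#' nNeurons(es); nEpochs(es)
#' @export
EpochedSpikes <- function(trains, neuronIds = NULL, epochIds = NULL,
                          labels = NULL, timeUnit = "samples",
                          metadata = list()) {
  M <- length(trains)
  N <- if (M > 0) length(trains[[1]]) else 0L
  trains <- lapply(trains, function(ep)
    lapply(ep, function(tr) sort(as.numeric(tr))))
  if (is.null(neuronIds))
    neuronIds <- sprintf("n%0*d", max(2L, nchar(N)), seq_len(N))
  if (is.null(epochIds))
    epochIds <- sprintf("e%0*d", max(2L, nchar(M)), seq_len(M))
  if (is.null(labels))
    labels <- data.frame(epoch_id = as.character(epochIds),
                         stringsAsFactors = FALSE)
  else if (!"epoch_id" %in% names(labels))
    labels <- cbind(data.frame(epoch_id = as.character(epochIds),
                               stringsAsFactors = FALSE), labels)
  new("EpochedSpikes", trains = trains,
      neuronIds = as.character(neuronIds),
      epochIds = as.character(epochIds), labels = labels,
      timeUnit = timeUnit, metadata = metadata)
}

#' Flow decomposition of the transport between two epochs
#'
#' Result of \code{\link{spikeShipPair}}: the optimal per-spike transport
#' shifts between two epochs, their decomposition into a global rigid
#' translation (the weighted median of all pooled flows) and neuron-specific
#' residual flows, and the resulting dissimilarity.  The shift convention is
#' \code{c = t_m - t_k} (second epoch minus first), so a positive global
#' shift means the second epoch's pattern occurs later.
#'
#' @slot dissimilarity mean over active neurons of the mass-weighted
#'   absolute neuron-specific flows (\code{NaN} when degenerate).
#' @slot globalShift the weighted median of all pooled flows (midpoint
#'   convention for tied intervals; \code{NaN} when degenerate).
#' @slot shifts,masses,neuron per-segment transport plan: signed shift,
#'   positive mass (summing to 1 within each neuron) and 1-based neuron
#'   index (empty unless flows were kept).
#' @slot activeSet 1-based indices of neurons with at least one spike in
#'   both epochs; only these enter the dissimilarity.
#' @slot perNeuronCost named per-active-neuron mass-weighted absolute
#'   residual flow.
#' @slot degenerate TRUE when no neuron is active in both epochs.
#' @slot epochPair the two epoch identifiers (k, m).
#' @export
setClass("FlowDecomposition",
  representation(dissimilarity = "numeric", globalShift = "numeric",
                 shifts = "numeric", masses = "numeric", neuron = "integer",
                 activeSet = "integer", perNeuronCost = "numeric",
                 degenerate = "logical", epochPair = "character"))

setValidity("FlowDecomposition", function(object) {
  if (length(object@shifts) != length(object@masses) ||
      length(object@shifts) != length(object@neuron))
    return("'shifts', 'masses' and 'neuron' must have equal length")
  if (any(object@masses <= 0)) return("segment masses must be positive")
  if (!object@degenerate && (is.nan(object@dissimilarity) ||
                             object@dissimilarity < 0))
    return("dissimilarity must be a non-negative number")
  TRUE
})

#' Pairwise dissimilarity matrices over all epochs
#'
#' Result of \code{\link{spikeShip}}: the symmetric epoch-by-epoch
#' dissimilarity matrix together with the companion matrix of global shifts
#' (\code{G[k, m]} = weighted-median flow of epoch m relative to epoch k,
#' antisymmetric under the midpoint tie convention).  Epoch pairs with no
#' commonly active neuron carry \code{NaN} in both matrices and are listed
#' in \code{degeneratePairs}.
#'
#' @slot FMatrix symmetric M x M non-negative dissimilarities, zero diagonal.
#' @slot GMatrix antisymmetric M x M global shifts, zero diagonal.
#' @slot epochIds epoch identifiers (also the dimnames of both matrices).
#' @slot degeneratePairs two-column integer matrix of degenerate pairs.
#' @export
setClass("DissimilarityResult",
  representation(FMatrix = "matrix", GMatrix = "matrix",
                 epochIds = "character", degeneratePairs = "matrix"))

setValidity("DissimilarityResult", function(object) {
  M <- length(object@epochIds)
  if (!all(dim(object@FMatrix) == c(M, M)) ||
      !all(dim(object@GMatrix) == c(M, M)))
    return("matrices must be M x M")
  if (any(diag(object@FMatrix) != 0) || any(diag(object@GMatrix) != 0))
    return("diagonals must be zero")
  ok <- !is.nan(object@FMatrix)
  if (any(object@FMatrix[ok] < 0)) return("dissimilarities must be >= 0")
  if (max(abs(object@FMatrix[ok] - t(object@FMatrix)[ok])) > 1e-9)
    return("FMatrix must be symmetric")
  TRUE
})
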
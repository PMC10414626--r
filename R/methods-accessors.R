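#' @rdname accessors
setMethod("nNeurons", "EpochedSpikes", function(x) length(x@neuronIds))

#' @rdname accessors
setMethod("nEpochs", "EpochedSpikes", function(x) length(x@epochIds))

#' @rdname accessors
setMethod("neuronIds", "EpochedSpikes", function(x) x@neuronIds)

#' @rdname accessors
setMethod("epochIds", "EpochedSpikes", function(x) x@epochIds)

#' @rdname accessors
setMethod("epochLabels", "EpochedSpikes", function(x) x@labels)

#' @rdname accessors
setMethod("epochLabels<-", "EpochedSpikes", function(x, value) {
  x@labels <- value
  validObject(x)
  x
})

#' @rdname accessors
setMethod("spikeTrains", "EpochedSpikes", function(x, epoch) {
  m <- .resolveEpoch(x, epoch)
  tr <- x@trains[[m]]
  names(tr) <- x@neuronIds
  tr
})

.resolveEpoch <- function(x, epoch) {
  if (is.character(epoch)) {
    m <- match(epoch, x@epochIds)
    if (is.na(m)) stop("unknown epoch id: ", epoch)
  } else {
    m <- as.integer(epoch)
    if (m < 1L || m > nEpochs(x)) stop("epoch index out of range: ", epoch)
  }
  m
}

#' Subset epochs and neurons
#'
#' \code{x[i, j]} keeps neurons \code{i} and epochs \code{j} (indices or
#' identifiers); labels rows follow the epochs.
#'
#' @param x an \code{\linkS4class{EpochedSpikes}} object.
#' @param i neuron indices or ids.
#' @param j epoch indices or ids.
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "EpochedSpikes", function(x, i, j, ..., drop = FALSE) {
  ni <- if (missing(i)) seq_along(x@neuronIds) else {
    if (is.character(i)) match(i, x@neuronIds) else i
  }
  nj <- if (missing(j)) seq_along(x@epochIds) else {
    if (is.character(j)) match(j, x@epochIds) else j
  }
  ni <- seq_along(x@neuronIds)[ni]
  nj <- seq_along(x@epochIds)[nj]
  if (anyNA(ni) || anyNA(nj)) stop("subscript out of bounds")
  new("EpochedSpikes",
      trains = lapply(x@trains[nj], function(ep) ep[ni]),
      neuronIds = x@neuronIds[ni], epochIds = x@epochIds[nj],
      labels = x@labels[nj, , drop = FALSE],
      timeUnit = x@timeUnit, metadata = x@metadata)
})

setMethod("show", "EpochedSpikes", function(object) {
  ns <- vapply(object@trains, function(ep) sum(lengths(ep)), numeric(1))
  cat("EpochedSpikes:", length(object@neuronIds), "neurons x",
      length(object@epochIds), "epochs (", object@timeUnit, ")\n")
  cat("  mean spikes per epoch:", format(mean(ns), digits = 4), "\n")
  extra <- setdiff(names(object@labels), "epoch_id")
  if (length(extra))
    cat("  label columns:", paste(extra, collapse = ", "), "\n")
})

#' @rdname accessors
setMethod("globalShift", "FlowDecomposition", function(x) x@globalShift)

#' @rdname accessors
setMethod("activeSet", "FlowDecomposition", function(x) x@activeSet)

#' @rdname accessors
setMethod("perNeuronCost", "FlowDecomposition", function(x) x@perNeuronCost)

#' @rdname accessors
setMethod("isDegenerate", "FlowDecomposition", function(x) x@degenerate)

#' @rdname accessors
setMethod("flowTable", "FlowDecomposition", function(x) {
  data.frame(epoch_k = x@epochPair[1], epoch_m = x@epochPair[2],
             neuron_id = names(x@perNeuronCost)[match(x@neuron, x@activeSet)],
             shift = x@shifts, mass = x@masses,
             stringsAsFactors = FALSE)
})

setMethod("show", "FlowDecomposition", function(object) {
  cat("FlowDecomposition", sprintf("(%s vs %s)\n", object@epochPair[1],
                                   object@epochPair[2]))
  if (object@degenerate) {
    cat("  degenerate: no neuron active in both epochs\n")
  } else {
    cat("  dissimilarity F :", format(object@dissimilarity, digits = 6), "\n")
    cat("  global shift    :", format(object@globalShift, digits = 6), "\n")
    cat("  active neurons  :", length(object@activeSet), "\n")
  }
})

#' @rdname accessors
setMethod("fMatrix", "DissimilarityResult", function(x) x@FMatrix)

#' @rdname accessors
setMethod("gMatrix", "DissimilarityResult", function(x) x@GMatrix)

#' @rdname accessors
setMethod("epochIds", "DissimilarityResult", function(x) x@epochIds)

setMethod("show", "DissimilarityResult", function(object) {
  M <- length(object@epochIds)
  off <- object@FMatrix[upper.tri(object@FMatrix)]
  cat("DissimilarityResult:", M, "x", M, "epochs\n")
  cat("  mean off-diagonal F:", format(mean(off, na.rm = TRUE), digits = 5),
      "\n")
  if (nrow(object@degeneratePairs))
    cat("  degenerate pairs  :", nrow(object@degeneratePairs), "\n")
})
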
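#' Accessors for spikeship containers
#'
#' Small accessor generics: \code{nNeurons} / \code{nEpochs} give grid
#' dimensions, \code{neuronIds} / \code{epochIds} the identifiers,
#' \code{epochLabels} the per-epoch annotation data.frame,
#' \code{spikeTrains} one epoch's list of per-neuron spike-time vectors,
#' \code{fMatrix} / \code{gMatrix} the dissimilarity and global-shift
#' matrices, \code{globalShift} / \code{activeSet} / \code{perNeuronCost} /
#' \code{isDegenerate} the components of a flow decomposition and
#' \code{flowTable} the transport plan as a long data.frame.
#'
#' @param x a package object.
#' @param epoch epoch identifier or index.
#' @param value replacement labels data.frame.
#' @name accessors
#' @aliases nNeurons nEpochs neuronIds epochIds epochLabels epochLabels<-
#'   spikeTrains fMatrix gMatrix globalShift activeSet perNeuronCost
#'   isDegenerate flowTable
NULL

#' @rdname accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))
#' @rdname accessors
#' @export
setGeneric("epochIds", function(x) standardGeneric("epochIds"))
#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @rdname accessors
#' @export
setGeneric("epochLabels<-", function(x, value) standardGeneric("epochLabels<-"))
#' @rdname accessors
#' @export
setGeneric("spikeTrains", function(x, epoch) standardGeneric("spikeTrains"))
#' @rdname accessors
#' @export
setGeneric("fMatrix", function(x) standardGeneric("fMatrix"))
#' @rdname accessors
#' @export
setGeneric("gMatrix", function(x) standardGeneric("gMatrix"))
#' @rdname accessors
#' @export
setGeneric("globalShift", function(x) standardGeneric("globalShift"))
#' @rdname accessors
#' @export
setGeneric("activeSet", function(x) standardGeneric("activeSet"))
#' @rdname accessors
#' @export
setGeneric("perNeuronCost", function(x) standardGeneric("perNeuronCost"))
#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))
#' @rdname accessors
#' @export
setGeneric("flowTable", function(x) standardGeneric("flowTable"))
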
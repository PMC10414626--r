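#' Read a long-format spike table
#'
#' Parses the canonical on-disk form of epoched spike data: a delimited
#' table with a header row and columns \code{epoch_id}, \code{neuron_id},
#' \code{spike_time}.  Times are sorted per (epoch, neuron); the full grid
#' is completed, so (epoch, neuron) combinations absent from the file become
#' empty trains.  Duplicate rows are kept — multiplicity is meaningful
#' mass.  Epoch and neuron order follow first appearance in the file, which
#' makes write-then-read round trips stable.
#'
#' @param path file path (CSV by default).
#' @param sep field separator.
#' @return \code{\linkS4class{EpochedSpikes}}.
#' @seealso \code{\link{writeSpikeTable}}
#' @export
readSpikeTable <- function(path, sep = ",") {
  if (!file.exists(path)) stop("readSpikeTable: no such file: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = "character")
  need <- c("epoch_id", "neuron_id", "spike_time")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("readSpikeTable: missing required column(s): ",
         paste(miss, collapse = ", "))
  tt <- suppressWarnings(as.numeric(df$spike_time))
  if (anyNA(tt) && nrow(df) > 0) {
    bad <- which(is.na(tt))[1]
    stop("readSpikeTable: non-numeric spike_time at data line ", bad,
         " ('", df$spike_time[bad], "')")
  }
  epochIds <- unique(df$epoch_id)
  neuronIds <- unique(df$neuron_id)
  ei <- match(df$epoch_id, epochIds)
  ni <- match(df$neuron_id, neuronIds)
  trains <- lapply(seq_along(epochIds), function(m) {
    ep <- rep(list(numeric(0)), length(neuronIds))
    inm <- which(ei == m)
    if (length(inm)) {
      sp <- split(tt[inm], ni[inm])
      for (g in names(sp)) ep[[as.integer(g)]] <- sort(sp[[g]])
    }
    ep
  })
  EpochedSpikes(trains, neuronIds = neuronIds, epochIds = epochIds)
}

#' Write a long-format spike table
#'
#' Inverse of \code{\link{readSpikeTable}}: epochs in object order, neurons
#' in object order within each epoch, times sorted — so sorted input
#' round-trips byte-stably.
#'
#' @param x \code{\linkS4class{EpochedSpikes}}.
#' @param path output file path.
#' @return invisibly, the written data.frame.
#' @export
writeSpikeTable <- function(x, path) {
  stopifnot(is(x, "EpochedSpikes"))
  rows <- lapply(seq_len(nEpochs(x)), function(m) {
    ep <- x@trains[[m]]
    n <- lengths(ep)
    data.frame(epoch_id = rep(x@epochIds[m], sum(n)),
               neuron_id = rep(x@neuronIds, n),
               spike_time = unlist(ep, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write / read a square matrix CSV with ids in header and first column
#'
#' @param mat square matrix with dimnames.
#' @param path file path.
#' @return \code{readMatrixCSV}: the matrix with dimnames restored.
#' @export
writeMatrixCSV <- function(mat, path) {
  df <- data.frame(epoch_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMatrixCSV
#' @export
readMatrixCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- list(ids, colnames(df)[-1])
  mat
}
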
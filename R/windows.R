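#' Sliding-window specification
#'
#' @param TW window length (> 0).
#' @param step hop between window starts; default half a window.
#' @param tStart,tEnd analysis span (\code{tStart < tEnd}).
#' @return validated list of class \code{"WindowSpec"}.
#' @export
windowSpec <- function(TW, step = TW / 2, tStart = 0, tEnd) {
  if (TW <= 0) stop("windowSpec: TW must be positive")
  if (step <= 0 || step > TW) stop("windowSpec: need 0 < step <= TW")
  if (tStart >= tEnd) stop("windowSpec: need tStart < tEnd")
  structure(list(TW = TW, step = step, tStart = tStart, tEnd = tEnd),
            class = "WindowSpec")
}

#' Epoch a continuous recording with sliding windows
#'
#' Slices a continuous multi-neuron recording into epochs, one per window
#' position.  Windows are half-open \code{[t, t + TW)} so tiling
#' (\code{step = TW}) assigns each boundary spike to exactly one window and
#' loses no spike within the span.  Spike times are re-expressed relative to
#' the window start; window start times are kept in the object's metadata
#' and as a \code{window_start} label column.
#'
#' @param spikes data.frame with columns \code{neuron_id} and
#'   \code{spike_time} (a continuous recording).
#' @param spec a \code{\link{windowSpec}}.
#' @param neuronIds optional neuron universe (defaults to the ids present);
#'   supply it to keep silent neurons in the grid.
#' @return \code{\linkS4class{EpochedSpikes}} with one epoch per window.
#' @export
epochsFromWindows <- function(spikes, spec, neuronIds = NULL) {
  stopifnot(inherits(spec, "WindowSpec"))
  if (!all(c("neuron_id", "spike_time") %in% names(spikes)))
    stop("epochsFromWindows: 'spikes' needs neuron_id and spike_time columns")
  if (is.null(neuronIds)) neuronIds <- unique(as.character(spikes$neuron_id))
  starts <- seq(spec$tStart, spec$tEnd - spec$TW, by = spec$step)
  if (length(starts) == 0)
    stop("epochsFromWindows: span shorter than one window")
  nid <- match(as.character(spikes$neuron_id), neuronIds)
  tt <- as.numeric(spikes$spike_time)
  trains <- lapply(starts, function(t0) {
    inw <- which(tt >= t0 & tt < t0 + spec$TW)
    ep <- rep(list(numeric(0)), length(neuronIds))
    if (length(inw)) {
      sp <- split(tt[inw] - t0, nid[inw])
      for (g in names(sp)) ep[[as.integer(g)]] <- sort(sp[[g]])
    }
    ep
  })
  EpochedSpikes(trains, neuronIds = neuronIds,
    epochIds = sprintf("w%0*d", max(2L, nchar(length(starts))),
                       seq_along(starts)),
    labels = data.frame(window_start = starts),
    metadata = list(windowSpec = spec, windowStarts = starts))
}

#' Cluster epochs from a precomputed dissimilarity matrix
#'
#' Label-assignment procedures operating directly on a dissimilarity
#' matrix.  The default is a classic density-based scan (DBSCAN) on the
#' precomputed distances: points with at least \code{minPts} neighbours
#' within \code{eps} are core points, density-connected cores form
#' clusters, everything else is labelled 0 (noise) — which matches the
#' generative structure of patterned epochs (dense clumps) plus homogeneous
#' noise epochs (diffuse).  When \code{eps} is not given it is placed in the
#' widest gap of the sorted \code{minPts}-th-neighbour distances, the usual
#' knee heuristic.  \code{"pam"} and \code{"hclust"} (average linkage) are
#' available when the number of clusters is known.
#'
#' @param D symmetric dissimilarity matrix (NaN-free).
#' @param method \code{"dbscan"}, \code{"pam"} or \code{"hclust"}.
#' @param k number of clusters (required for pam / hclust).
#' @param minPts DBSCAN core-point threshold (counting the point itself).
#' @param eps DBSCAN neighbourhood radius; default data-driven as above.
#' @return integer labels, length M; 0 marks DBSCAN noise.
#' @export
clusterEpochs <- function(D, method = c("dbscan", "pam", "hclust"),
                          k = NULL, minPts = 6, eps = NULL) {
  method <- match.arg(method)
  D <- as.matrix(D)
  if (any(is.nan(D))) stop("clusterEpochs: D contains NaN (degenerate pairs)")
  M <- nrow(D)
  if (method == "pam") {
    if (is.null(k)) stop("clusterEpochs: pam needs k")
    return(as.integer(cluster::pam(as.dist(D), k, diss = TRUE,
                                   cluster.only = TRUE)))
  }
  if (method == "hclust") {
    if (is.null(k)) stop("clusterEpochs: hclust needs k")
    return(as.integer(cutree(hclust(as.dist(D), method = "average"), k)))
  }
  if (is.null(eps)) eps <- .epsKnee(D, minPts)
  .dbscanMatrix(D, eps, minPts)
}

# kth-nearest-neighbour knee: widest gap in the sorted kNN distances.
.epsKnee <- function(D, minPts) {
  M <- nrow(D)
  kth <- min(minPts, M - 1)
  knn <- sort(vapply(seq_len(M), function(i) sort(D[i, -i])[kth], numeric(1)))
  gaps <- diff(knn)
  j <- which.max(gaps)
  knn[j] + gaps[j] / 2
}

# Classic DBSCAN on a precomputed distance matrix (no density-based
# clustering package is available as a dependency, and the matrix is small).
.dbscanMatrix <- function(D, eps, minPts) {
  M <- nrow(D)
  nb <- lapply(seq_len(M), function(i) which(D[i, ] <= eps))  # incl. self
  core <- lengths(nb) >= minPts
  labels <- integer(M)
  cl <- 0L
  for (i in seq_len(M)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Mean silhouette width on a precomputed dissimilarity matrix
#'
#' Silhouette computed directly on the dissimilarity matrix (no embedding
#' step), so the score is deterministic and free of embedding distortion.
#' DBSCAN noise labels (0) are treated as one extra cluster.  Returns
#' \code{NA} when fewer than two clusters are present.
#'
#' @param D symmetric dissimilarity matrix.
#' @param labels integer cluster labels (0 allowed for noise).
#' @return mean silhouette width in [-1, 1], or NA.
#' @export
silhouetteScore <- function(D, labels) {
  D <- as.matrix(D)
  labels <- as.integer(labels)
  labels[labels == 0L] <- max(labels) + 1L
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(labels, dmatrix = D)
  mean(sil[, "sil_width"])
}

#' Select the sliding-window length by silhouette score
#'
#' For each candidate window length: epoch the recording, compute the
#' SpikeShip dissimilarity matrix, drop epochs involved in degenerate pairs,
#' assign cluster labels with a pluggable procedure (default
#' \code{\link{clusterEpochs}}, density-based) and score the mean silhouette
#' width directly on the dissimilarity matrix.  The winner is the candidate
#' with the highest score (ties go to the shorter window); candidates that
#' yield fewer than two usable epochs or a single cluster are scored
#' missing, never zero.
#'
#' @param spikes continuous recording: data.frame with \code{neuron_id},
#'   \code{spike_time}.
#' @param candidates numeric vector (>= 2 suggested) of window lengths.
#' @param tStart,tEnd analysis span; defaults to the recording extent.
#' @param step hop size, default half the candidate window.
#' @param clusterer function(D) -> integer labels; default density-based.
#' @param seed seed passed to \code{set.seed} before each clustering call.
#' @return list with \code{best} (winning window length) and \code{scores}
#'   (data.frame: TW, nEpochs, nClusters, silhouette).
#' @export
selectWindowLength <- function(spikes, candidates, tStart = NULL,
                               tEnd = NULL, step = NULL,
                               clusterer = clusterEpochs, seed = 1L) {
  if (length(candidates) < 1) stop("selectWindowLength: no candidates")
  if (is.null(tStart)) tStart <- min(spikes$spike_time)
  if (is.null(tEnd)) tEnd <- max(spikes$spike_time) + 1e-9
  neuronIds <- unique(as.character(spikes$neuron_id))
  scores <- lapply(candidates, function(TW) {
    if (tEnd - tStart < TW)
      return(data.frame(TW = TW, nEpochs = 0L, nClusters = NA_integer_,
                        silhouette = NA_real_))
    sp <- windowSpec(TW, step = if (is.null(step)) TW / 2 else step,
                     tStart = tStart, tEnd = tEnd)
    es <- epochsFromWindows(spikes, sp, neuronIds = neuronIds)
    if (nEpochs(es) < 2)
      return(data.frame(TW = TW, nEpochs = nEpochs(es),
                        nClusters = NA_integer_, silhouette = NA_real_))
    res <- suppressMessages(spikeShip(es))
    Fm <- fMatrix(res)
    keep <- .dropDegenerate(Fm)
    if (length(keep) < 2)
      return(data.frame(TW = TW, nEpochs = length(keep),
                        nClusters = NA_integer_, silhouette = NA_real_))
    Fm <- Fm[keep, keep]
    set.seed(seed)
    labels <- clusterer(Fm)
    nc <- length(unique(labels[labels != 0]))
    data.frame(TW = TW, nEpochs = length(keep), nClusters = nc,
               silhouette = silhouetteScore(Fm, labels))
  })
  scores <- do.call(rbind, scores)
  ok <- which(!is.na(scores$silhouette))
  best <- if (length(ok)) scores$TW[ok[which.max(scores$silhouette[ok])]]
          else NA_real_
  list(best = best, scores = scores)
}

# Greedily drop the epoch with most NaN pairs until the matrix is NaN-free.
.dropDegenerate <- function(Fm) {
  keep <- seq_len(nrow(Fm))
  repeat {
    bad <- rowSums(is.nan(Fm[keep, keep, drop = FALSE]))
    if (!any(bad > 0)) return(keep)
    keep <- keep[-which.max(bad)]
    if (length(keep) < 2) return(keep)
  }
}
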